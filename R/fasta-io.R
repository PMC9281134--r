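#' Write a transcript table to FASTA
#'
#' Headers carry `gene=` and `isoform=` attributes when the corresponding
#' columns are present, so a round trip through [read_transcript_fasta()]
#' restores them.
#'
#' @param transcripts tibble with at least `id` and `sequence` columns;
#'   `gene_id` and `isoform` columns are serialized into the header.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  stopifnot(all(c("id", "sequence") %in% names(transcripts)))
  hdr <- transcripts$id
  if ("gene_id" %in% names(transcripts)) {
    hdr <- ifelse(is.na(transcripts$gene_id), hdr,
                  paste0(hdr, " gene=", transcripts$gene_id))
  }
  if ("isoform" %in% names(transcripts)) {
    hdr <- ifelse(is.na(transcripts$isoform), hdr,
                  paste0(hdr, " isoform=", transcripts$isoform))
  }
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80)
  invisible(path)
}

#' Read a FASTA file into a transcript tibble
#'
#' @param path FASTA file. Header fields `gene=` and `isoform=` (as written by
#'   [write_transcript_fasta()]) are parsed back into columns.
#' @return tibble with columns `id`, `gene_id`, `isoform`, `sequence`, `length`.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    has <- grepl(paste0(key, "="), hdr)
    out[has] <- sub(paste0("^", key, "="), "", m)
    out
  }
  tibble::tibble(
    id = id,
    gene_id = grab("gene"),
    isoform = grab("isoform"),
    sequence = unname(as.character(seqs)),
    length = Biostrings::width(seqs)
  )
}

# named character vector of sequence lengths from a transcript tibble
transcript_lengths <- function(transcripts) {
  setNames(nchar(transcripts$sequence), transcripts$id)
}
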