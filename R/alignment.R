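HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), align_len = integer(), mismatches = integer(),
    gap_opens = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric()
  )
}

#' Read a 12-column tabular alignment hit file
#'
#' Reads the common tab-separated pairwise-alignment dialect (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Query coordinates are 1-based inclusive with `q_start <= q_end`; subject
#' hits with `s_start > s_end` encode the minus strand and are retained.
#'
#' @param path file path; an empty file yields an empty hit tibble.
#' @param query_lengths,subject_lengths optional named vectors used to
#'   validate coordinates against sequence lengths; malformed rows are
#'   reported with their line numbers.
#' @return tibble of alignment hits.
#' @export
read_hit_table <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  if (!file.exists(path)) stop_validation(paste0("no such hit table: ", path))
  if (file.size(path) == 0) return(empty_hits())
  hits <- readr::read_tsv(
    path, col_names = HIT_COLUMNS,
    col_types = readr::cols(
      query_id = "c", subject_id = "c", pct_identity = "d", align_len = "i",
      mismatches = "i", gap_opens = "i", q_start = "i", q_end = "i",
      s_start = "i", s_end = "i", evalue = "d", bitscore = "d"
    ),
    progress = FALSE
  )
  validate_hits(hits, query_lengths, subject_lengths)
  hits
}

validate_hits <- function(hits, query_lengths = NULL, subject_lengths = NULL) {
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop_validation(sprintf("%s in row(s) %s", what,
                              paste(head(rows, 5), collapse = ", ")))
    }
  }
  bad_row(!(hits$q_start >= 1 & hits$q_start <= hits$q_end),
          "invalid query coordinates")
  bad_row(hits$align_len < 1, "alignment length < 1")
  bad_row(hits$evalue < 0, "negative e-value")
  bad_row(pmin(hits$s_start, hits$s_end) < 1, "subject coordinate < 1")
  if (!is.null(query_lengths)) {
    ql <- unname(query_lengths[hits$query_id])
    bad_row(is.na(ql) | hits$q_end > ql, "q_end beyond query length")
  }
  if (!is.null(subject_lengths)) {
    sl <- unname(subject_lengths[hits$subject_id])
    bad_row(is.na(sl) | pmax(hits$s_start, hits$s_end) > sl,
            "subject coordinate beyond subject length")
  }
  invisible(hits)
}

#' Write alignment hits as a 12-column tabular file
#'
#' @param hits tibble of hits as returned by [read_hit_table()] or
#'   [seed_extend_align()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, HIT_COLUMNS], path, col_names = FALSE)
  invisible(path)
}

#' Desk-scale seed-and-extend nucleotide search
#'
#' Exact k-mer seeding with ungapped X-drop extension, sufficient for the
#' substitution-only synthetic assemblies this package simulates; real-data
#' users supply externally computed hit tables instead. E-values follow a
#' Karlin-Altschul-style model `E = m * n * 2^(-bitscore)` with `m`, `n` the
#' total query and subject lengths, so only relative ranking is meaningful.
#'
#' @param queries,subjects transcript tibbles (columns `id`, `sequence`) or
#'   named character vectors of sequences.
#' @param word_size exact-match seed length (>= 8).
#' @param min_align_len minimum reported alignment length.
#' @param max_evalue e-value cutoff; the underlying study does not state one
#'   for these searches, so this is plain configuration.
#' @param strand `"both"` searches the subject minus strand too (reported
#'   with `s_start > s_end`); `"plus"` skips it.
#' @param match,mismatch,xdrop ungapped scoring parameters.
#' @return tibble of alignment hits, ordered by query, e-value, bitscore.
#' @export
seed_extend_align <- function(queries, subjects, word_size = 11,
                              min_align_len = 50, max_evalue = 1e-6,
                              strand = c("both", "plus"),
                              match = 1, mismatch = 2, xdrop = 20) {
  strand <- match.arg(strand)
  if (word_size < 8) stop_config("word_size must be >= 8")
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$sequence, x$id) else x
  }
  q <- as_named(queries); s <- as_named(subjects)
  if (length(q) == 0 || length(s) == 0) return(empty_hits())

  run <- function(subj_seq) {
    .cpp_seed_extend(unname(q), unname(subj_seq), as.integer(word_size),
                     as.integer(min_align_len), max_evalue,
                     as.integer(match), as.integer(mismatch),
                     as.integer(xdrop))
  }
  plus <- tibble::as_tibble(run(s))
  plus$strand <- "+"
  out <- plus
  if (strand == "both") {
    minus <- tibble::as_tibble(run(revcomp(unname(s))))
    if (nrow(minus) > 0) {
      slen <- nchar(unname(s))[minus$subject_idx]
      tmp_start <- slen - minus$s_end + 1
      tmp_end <- slen - minus$s_start + 1
      minus$s_start <- tmp_end   # s_start > s_end encodes minus strand
      minus$s_end <- tmp_start
      minus$strand <- "-"
      out <- dplyr::bind_rows(plus, minus)
    }
  }
  if (nrow(out) == 0) return(empty_hits())
  out |>
    dplyr::mutate(
      query_id = names(q)[.data$query_idx],
      subject_id = names(s)[.data$subject_idx],
      gap_opens = 0L
    ) |>
    # drop exact strand duplicates of palindromic self-hits
    dplyr::arrange(.data$query_idx, .data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_idx) |>
    dplyr::select(dplyr::all_of(HIT_COLUMNS)) |>
    dplyr::mutate(dplyr::across(c("align_len", "mismatches", "gap_opens",
                                  "q_start", "q_end", "s_start", "s_end"),
                                as.integer))
}
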