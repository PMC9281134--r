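#' Best two subjects of one query, with merged query intervals
#'
#' Ranks the subjects of one query's hits by their best hit (e-value
#' ascending, bitscore descending, subject id as final tie-break) and merges
#' each subject's hits into one spanning query interval, since local
#' alignments fragment across mutations. At most the best two subjects are
#' returned, mirroring a best-two reference search.
#'
#' @param hits hit tibble for a single query.
#' @return tibble with <= 2 rows: subject_id, rank, merged `q_start`/`q_end`,
#'   merged subject span `s_lo`/`s_hi`, `strand`, best e-value/bitscore and
#'   the number of merged hits. Empty hit input gives an empty tibble.
#' @export
top_two_subjects <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      query_id = character(), subject_id = character(), rank = integer(),
      q_start = integer(), q_end = integer(), s_lo = integer(),
      s_hi = integer(), strand = character(), best_evalue = numeric(),
      best_bitscore = numeric(), n_hits = integer()))
  }
  if (dplyr::n_distinct(hits$query_id) != 1)
    stop_validation("top_two_subjects expects hits of a single query")
  hits |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::summarise(
      q_start = min(.data$q_start), q_end = max(.data$q_end),
      s_lo = min(pmin(.data$s_start, .data$s_end)),
      s_hi = max(pmax(.data$s_start, .data$s_end)),
      strand = ifelse(.data$s_start <= .data$s_end, "+", "-")[
        order(.data$evalue, -.data$bitscore)[1]],
      best_evalue = min(.data$evalue),
      best_bitscore = max(.data$bitscore[.data$evalue == min(.data$evalue)]),
      n_hits = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$best_evalue, dplyr::desc(.data$best_bitscore),
                   .data$subject_id) |>
    dplyr::slice_head(n = 2) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "subject_id")
}

#' Detect a chimeric transcript from its best two reference subjects
#'
#' A transcript is called chimeric when its two best reference subjects fit
#' different regions of the query: the merged intervals overlap by less than
#' `max_overlap_frac` of the shorter interval, both intervals are at least
#' `min_interval` nt, and the two subjects belong to different reference
#' genes (isoforms of one gene signal isoform structure, not misassembly).
#'
#' @param tx_length transcript length in nt.
#' @param top_two result of [top_two_subjects()]; needs exactly two subjects
#'   for a call to be possible.
#' @param subject_lengths named vector of reference sequence lengths.
#' @param min_interval minimum merged-interval length per subject.
#' @param max_overlap_frac maximum interval overlap as a fraction of the
#'   shorter interval ("different regions" criterion).
#' @param subject_genes optional named vector mapping subject ids to gene
#'   ids; defaults to stripping a trailing `.N` isoform suffix.
#' @return one-row tibble (a chimera call, `overlap_len` negative for a gap)
#'   or `NULL`.
#' @export
detect_chimera <- function(tx_length, top_two, subject_lengths,
                           min_interval = 100, max_overlap_frac = 0.5,
                           subject_genes = NULL) {
  if (nrow(top_two) < 2) return(NULL)
  genes <- if (is.null(subject_genes)) infer_gene_id(top_two$subject_id)
           else unname(subject_genes[top_two$subject_id])
  if (genes[1] == genes[2]) return(NULL)
  tt <- top_two[order(top_two$q_start, top_two$q_end), ]
  len1 <- tt$q_end[1] - tt$q_start[1] + 1
  len2 <- tt$q_end[2] - tt$q_start[2] + 1
  overlap <- min(tt$q_end[1], tt$q_end[2]) - tt$q_start[2] + 1
  if (len1 < min_interval || len2 < min_interval) return(NULL)
  if (overlap >= max_overlap_frac * min(len1, len2)) return(NULL)
  tibble::tibble(
    transcript_id = tt$query_id[1], tx_length = as.integer(tx_length),
    subject_1 = tt$subject_id[1], subject_2 = tt$subject_id[2],
    subject_len_1 = as.integer(unname(subject_lengths[tt$subject_id[1]])),
    subject_len_2 = as.integer(unname(subject_lengths[tt$subject_id[2]])),
    q_start_1 = tt$q_start[1], q_end_1 = tt$q_end[1],
    q_start_2 = tt$q_start[2], q_end_2 = tt$q_end[2],
    s_lo_1 = tt$s_lo[1], s_hi_1 = tt$s_hi[1], strand_1 = tt$strand[1],
    s_lo_2 = tt$s_lo[2], s_hi_2 = tt$s_hi[2], strand_2 = tt$strand[2],
    overlap_len = as.integer(overlap)
  )
}

#' Compute split positions for a chimera call
#'
#' Applies the splitting rule: if the two reference hits overlap by less than
#' `overlap_threshold` nucleotides (gaps included), the transcript is split
#' at the floor midpoint of the overlap (or gap) region; otherwise the cut
#' points are the corrected end of part 1 and corrected start of part 2,
#' extrapolated from the unaligned reference tails, strand-aware.
#'
#' @param call chimera call tibble from [detect_chimera()] (one or more rows).
#' @param overlap_threshold overlap below which the midpoint rule applies
#'   (150 nt).
#' @return the call tibble completed with `split_kind` (`midpoint` or
#'   `corrected_boundary`), `split_1` and `split_2` (`NA` for midpoint).
#' @export
compute_split <- function(call, overlap_threshold = 150) {
  down_tail <- function(strand, s_lo, s_hi, slen)
    ifelse(strand == "+", slen - s_hi, s_lo - 1)
  up_tail <- function(strand, s_lo, s_hi, slen)
    ifelse(strand == "+", s_lo - 1, slen - s_hi)

  midpoint <- call$overlap_len < overlap_threshold
  lo <- ifelse(call$overlap_len >= 1, call$q_start_2, call$q_end_1 + 1)
  hi <- ifelse(call$overlap_len >= 1, call$q_start_2 + call$overlap_len - 1,
               call$q_start_2 - 1)
  mid <- pmin(pmax((lo + hi) %/% 2, 1L), call$tx_length - 1L)
  c_end_1 <- pmin(call$tx_length,
                  call$q_end_1 + down_tail(call$strand_1, call$s_lo_1,
                                           call$s_hi_1, call$subject_len_1))
  c_start_2 <- pmax(1L, call$q_start_2 - up_tail(call$strand_2, call$s_lo_2,
                                                 call$s_hi_2,
                                                 call$subject_len_2))
  call$split_kind <- ifelse(midpoint, "midpoint", "corrected_boundary")
  call$split_1 <- as.integer(ifelse(midpoint, mid, c_end_1))
  call$split_2 <- as.integer(ifelse(midpoint, NA_integer_, c_start_2))
  call
}

#' Split a transcript sequence according to a completed chimera call
#'
#' Midpoint splits cut into `[1, m]` and `[m + 1, L]` (concatenation equals
#' the original); corrected-boundary splits cut into `[1, corrected_end_1]`
#' and `[corrected_start_2, L]`, which may overlap but always cover the
#' original. Degenerate fragments (< 1 nt) leave the transcript unsplit with
#' a warning.
#'
#' @param id,sequence transcript identifier and sequence.
#' @param call one-row completed call from [compute_split()].
#' @return tibble of the resulting transcripts (`_split1`/`_split2` suffixes
#'   and a `split_from` provenance column), or the original transcript.
#' @export
split_transcript <- function(id, sequence, call) {
  L <- nchar(sequence)
  if (call$split_kind == "midpoint") {
    e1 <- call$split_1; s2 <- call$split_1 + 1L
    bad <- is.na(e1) || e1 < 1 || e1 >= L
  } else {
    e1 <- call$split_1; s2 <- call$split_2
    bad <- is.na(e1) || is.na(s2) || e1 < 1 || s2 > L
  }
  if (bad) {
    warning(sprintf("degenerate split for %s; left unsplit", id))
    return(tibble::tibble(id = id, sequence = sequence,
                          split_from = NA_character_))
  }
  parent_id <- id
  tibble::tibble(
    id = paste0(parent_id, c("_split1", "_split2")),
    sequence = c(substr(sequence, 1, e1), substr(sequence, s2, L)),
    split_from = parent_id
  )
}

#' Resolve chimeras in an assembly against a reference hit table
#'
#' Runs detection and splitting over a whole transcript set: every detected
#' chimera is replaced by its two fragments, everything else passes through
#' untouched.
#'
#' @param transcripts transcript tibble (`id`, `sequence`).
#' @param hits hit table of the transcripts (queries) vs the reference
#'   (subjects).
#' @param subject_lengths named vector of reference sequence lengths.
#' @inheritParams detect_chimera
#' @inheritParams compute_split
#' @return list with `transcripts` (the resolved set; fragments carry
#'   `split_from`) and `report` (one row per call with its evidence and
#'   split positions).
#' @export
resolve_assembly <- function(transcripts, hits, subject_lengths,
                             overlap_threshold = 150, min_interval = 100,
                             max_overlap_frac = 0.5, subject_genes = NULL) {
  tx_len <- setNames(nchar(transcripts$sequence), transcripts$id)
  calls <- list()
  if (nrow(hits) > 0) {
    multi <- hits |>
      dplyr::distinct(.data$query_id, .data$subject_id) |>
      dplyr::count(.data$query_id) |>
      dplyr::filter(.data$n >= 2) |>
      dplyr::pull(.data$query_id)
    by_query <- split(hits[hits$query_id %in% multi, ],
                      hits$query_id[hits$query_id %in% multi])
    calls <- purrr::map(by_query, function(h) {
      q <- h$query_id[1]
      detect_chimera(tx_len[[q]], top_two_subjects(h), subject_lengths,
                     min_interval = min_interval,
                     max_overlap_frac = max_overlap_frac,
                     subject_genes = subject_genes)
    }) |> purrr::compact()
  }
  if (length(calls) == 0) {
    out <- transcripts[, c("id", "sequence")]
    out$split_from <- NA_character_
    out$length <- nchar(out$sequence)
    empty_report <- tibble::tibble(
      transcript_id = character(), tx_length = integer(),
      subject_1 = character(), subject_2 = character(),
      q_start_1 = integer(), q_end_1 = integer(),
      q_start_2 = integer(), q_end_2 = integer(),
      overlap_len = integer(), split_kind = character(),
      split_1 = integer(), split_2 = integer())
    return(list(transcripts = out, report = empty_report))
  }
  report <- compute_split(dplyr::bind_rows(calls),
                          overlap_threshold = overlap_threshold)
  seq_of <- setNames(transcripts$sequence, transcripts$id)
  frags <- purrr::map_dfr(seq_len(nrow(report)), function(i) {
    split_transcript(report$transcript_id[i],
                     seq_of[[report$transcript_id[i]]], report[i, ])
  })
  untouched <- transcripts[!transcripts$id %in% report$transcript_id,
                           c("id", "sequence")]
  untouched$split_from <- NA_character_
  out <- dplyr::bind_rows(untouched, frags)
  out$length <- nchar(out$sequence)
  list(transcripts = out, report = report)
}
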