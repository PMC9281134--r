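norm_rna <- function(x) toupper(gsub("U", "T", toupper(x)))

#' Collapse mature miRNAs into <= 1-mismatch groups
#'
#' Mature sequences differing by at most one nucleotide are combined into one
#' counting group to avoid multiple mapping during read counting: groups are
#' the connected components of the graph linking equal-length sequences at
#' Hamming distance <= 1 (identical sequences merged), applied transitively.
#'
#' @param mature tibble with `name` and `sequence` (18-26 nt over A/C/G/T/U).
#' @return tibble with one row per group: `group_id` (member names joined by
#'   `/`), `members` (list of names), `sequences` (list), `n_members`.
#' @export
collapse_mature_mirnas <- function(mature) {
  seqs <- norm_rna(mature$sequence)
  if (any(grepl("[^ACGT]", seqs)))
    stop_validation("mature sequences must be over A/C/G/T/U")
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (hamming(seqs[i], seqs[j]) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), root) |>
    purrr::map_dfr(function(idx) {
      nm <- sort(mature$name[idx])
      tibble::tibble(
        group_id = paste(nm, collapse = "/"),
        members = list(nm),
        sequences = list(unique(seqs[idx])),
        n_members = length(idx)
      )
    }) |>
    dplyr::arrange(.data$group_id)
}

# Does read r (ACGT) match member m allowing <= max_mm substitutions, with the
# shorter sequence contained full-length in the longer at some offset?
match_one <- function(r, m, max_mm = 1) {
  lr <- nchar(r); lm <- nchar(m)
  if (lr == lm) return(hamming(r, m) <= max_mm)
  short <- if (lr < lm) r else m
  long <- if (lr < lm) m else r
  ls <- nchar(short); ll <- nchar(long)
  for (off in 0:(ll - ls)) {
    if (hamming(short, substr(long, off + 1, off + ls)) <= max_mm) return(TRUE)
  }
  FALSE
}

#' Count small-RNA reads per miRNA group per sample
#'
#' A read counts for a group iff it matches some member full-length (the
#' shorter of read and member contained in the longer) with at most
#' `max_mismatch` substitutions. Reads matching members of more than one
#' group are discarded and logged; presence means count >= 1.
#'
#' @param reads tibble with `sample` and `sequence` (18-26 nt).
#' @param groups group table from [collapse_mature_mirnas()].
#' @param max_mismatch substitution tolerance (1).
#' @return list with `counts` (tibble group_id x sample, long format),
#'   `matrix` (groups x samples), `presence` (named logical matrix),
#'   `stats` (per sample: total, assigned, ambiguous, unmatched).
#' @export
match_reads_to_groups <- function(reads, groups, max_mismatch = 1) {
  wid <- nchar(reads$sequence)
  if (any(wid < 18 | wid > 26))
    stop_validation("reads must be 18-26 nt (trimmed small-RNA length range)")
  uread <- reads |>
    dplyr::mutate(sequence = norm_rna(.data$sequence)) |>
    dplyr::count(.data$sample, .data$sequence, name = "n")
  uniq <- unique(uread$sequence)

  assign_of <- vapply(uniq, function(r) {
    hit <- which(vapply(groups$sequences, function(ms)
      any(vapply(ms, match_one, logical(1), r = r, max_mm = max_mismatch)),
      logical(1)))
    if (length(hit) == 1) hit else if (length(hit) == 0) 0L else -1L
  }, integer(1))

  uread$group_idx <- unname(assign_of[uread$sequence])
  samples <- sort(unique(reads$sample))
  mat <- matrix(0L, nrow(groups), length(samples),
                dimnames = list(groups$group_id, samples))
  assigned <- uread[uread$group_idx > 0, ]
  if (nrow(assigned) > 0) {
    agg <- assigned |>
      dplyr::group_by(.data$sample, .data$group_idx) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    mat[cbind(agg$group_idx, match(agg$sample, samples))] <- agg$n
  }
  stats <- uread |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      total = sum(.data$n),
      assigned = sum(.data$n[.data$group_idx > 0]),
      ambiguous = sum(.data$n[.data$group_idx == -1]),
      unmatched = sum(.data$n[.data$group_idx == 0]),
      .groups = "drop"
    )
  counts_long <- tibble::as_tibble(mat, rownames = "group_id") |>
    tidyr::pivot_longer(-"group_id", names_to = "sample", values_to = "count")
  list(counts = counts_long, matrix = mat, presence = mat >= 1, stats = stats)
}

#' Ortholog miRNA groups across two species
#'
#' A miRNA group is an ortholog between the species when reads of both
#' species match it, i.e. both map to the same reference mature miRNA group.
#'
#' @param presence_a,presence_b named logical vectors (group present in the
#'   species, any sample) or presence matrices from
#'   [match_reads_to_groups()] (a group is present if seen in any sample).
#' @return character vector of shared group ids.
#' @export
mirna_orthologs <- function(presence_a, presence_b) {
  as_vec <- function(p) {
    if (is.matrix(p)) apply(p, 1, any) else p
  }
  pa <- as_vec(presence_a); pb <- as_vec(presence_b)
  if (!setequal(names(pa), names(pb)))
    stop_validation("presence maps must cover the same group universe")
  pb <- pb[names(pa)]
  sort(names(pa)[pa & pb])
}
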