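#' Co-best subject sets per query
#'
#' For each query, returns every subject whose best hit ties the query's top
#' (e-value, bitscore, alignment length) triple — the "best hits" definition
#' under which several subjects can be co-best.
#'
#' @param hits hit tibble (one search direction).
#' @return tibble with one row per (query, co-best subject) plus the tying
#'   hit's e-value, bitscore and alignment length. Queries without hits are
#'   absent.
#' @export
best_hit_sets <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = numeric(), bitscore = numeric(),
                          align_len = integer()))
  }
  hits |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$align_len), .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$evalue == min(.data$evalue)) |>
    dplyr::filter(.data$bitscore == max(.data$bitscore)) |>
    dplyr::filter(.data$align_len == max(.data$align_len)) |>
    dplyr::ungroup() |>
    dplyr::select("query_id", "subject_id", "evalue", "bitscore", "align_len")
}

#' Reciprocal best hit candidate pairs
#'
#' Emits the pair (a, b) whenever b is among a's co-best subjects in the
#' A-to-B search and a is among b's co-best subjects in the B-to-A search.
#' Ties produce multiple candidate pairs; pruning resolves them to 1:1.
#'
#' @param best_a2b,best_b2a co-best sets from [best_hit_sets()] for the two
#'   search directions.
#' @return tibble of candidate pairs `id_a`, `id_b` with the A-to-B best
#'   hit's alignment length and bitscore.
#' @export
reciprocal_best_pairs <- function(best_a2b, best_b2a) {
  fwd <- dplyr::rename(best_a2b, id_a = "query_id", id_b = "subject_id")
  rev <- dplyr::select(best_b2a, id_b = "query_id", id_a = "subject_id")
  dplyr::inner_join(fwd, rev, by = c("id_a", "id_b")) |>
    dplyr::select("id_a", "id_b", align_len_ab = "align_len",
                  bitscore = "bitscore", evalue = "evalue")
}

#' Filter candidate pairs on alignment length and length ratio
#'
#' Keeps pairs with a cross-species alignment longer than `min_align_len`
#' nucleotides (strictly) whose shorter transcript is at least
#' `min_length_ratio` of the longer one.
#'
#' @param candidates pairs from [reciprocal_best_pairs()].
#' @param lengths named vector of transcript lengths for both species.
#' @param min_align_len strict lower bound for alignment length (250).
#' @param min_length_ratio minimum shorter/longer transcript length ratio (0.5).
#' @return list with `pairs` (kept, with `len_a`/`len_b` attached) and
#'   `excluded` (dropped pairs with a `reason`).
#' @export
filter_pairs <- function(candidates, lengths, min_align_len = 250,
                         min_length_ratio = 0.5) {
  miss <- setdiff(unique(c(candidates$id_a, candidates$id_b)), names(lengths))
  if (length(miss) > 0)
    stop_validation(paste0("missing transcript length for: ",
                           paste(head(miss, 3), collapse = ", ")))
  x <- candidates |>
    dplyr::mutate(
      len_a = unname(lengths[.data$id_a]),
      len_b = unname(lengths[.data$id_b]),
      length_ratio = pmin(.data$len_a, .data$len_b) /
        pmax(.data$len_a, .data$len_b),
      reason = dplyr::case_when(
        align_len_ab <= min_align_len ~ "alignment_too_short",
        length_ratio < min_length_ratio ~ "length_ratio_below_minimum",
        TRUE ~ NA_character_
      )
    )
  list(pairs = dplyr::select(dplyr::filter(x, is.na(.data$reason)), -"reason"),
       excluded = dplyr::filter(x, !is.na(.data$reason)))
}

#' Assign each transcript its best reference gene
#'
#' The single best reference hit (e-value, then bitscore, then lexicographic
#' subject id) determines the gene; transcripts without a hit map to `NA`.
#'
#' @param hits_vs_ref hit table of transcripts (queries) vs the reference.
#' @param subject_genes optional named subject-to-gene map; defaults to
#'   stripping a trailing `.N` isoform suffix from the subject id.
#' @return tibble `id`, `ref_gene`, `ref_subject`, `ref_bitscore`.
#' @export
assign_reference_gene <- function(hits_vs_ref, subject_genes = NULL) {
  if (nrow(hits_vs_ref) == 0)
    return(tibble::tibble(id = character(), ref_gene = character(),
                          ref_subject = character(), ref_bitscore = numeric()))
  hits_vs_ref |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      id = .data$query_id,
      ref_gene = if (is.null(subject_genes)) infer_gene_id(.data$subject_id)
                 else unname(subject_genes[.data$subject_id]),
      ref_subject = .data$subject_id,
      ref_bitscore = .data$bitscore
    )
}

#' Prune isoform-redundant pairs to the final 1:1 ortholog-transcriptome
#'
#' Per reference gene and species, at most one transcript is retained, chosen
#' by the longest cross-species alignment (ties by bitscore, then
#' lexicographic pair id); isoforms fitting different reference genes coexist.
#' Every retained transcript ends up in exactly one pair. Pairs are named by
#' the reference gene id of their members (species A precedence when the two
#' species' assignments disagree, logged as a conflict), or sequentially
#' numbered when neither member has a reference hit.
#'
#' @param pairs filtered pairs from [filter_pairs()].
#' @param ref_a,ref_b reference assignments from [assign_reference_gene()]
#'   for species A and B transcripts.
#' @return list with `pairs` (final 1:1 table: `final_name`, ids, reference
#'   genes, alignment stats, `naming_conflict` flag) and `excluded`
#'   (pruned pairs with reasons).
#' @export
prune_isoforms <- function(pairs, ref_a, ref_b) {
  x <- pairs |>
    dplyr::left_join(dplyr::select(ref_a, id_a = "id", ref_gene_a = "ref_gene"),
                     by = "id_a") |>
    dplyr::left_join(dplyr::select(ref_b, id_b = "id", ref_gene_b = "ref_gene"),
                     by = "id_b") |>
    dplyr::arrange(dplyr::desc(.data$align_len_ab), dplyr::desc(.data$bitscore),
                   .data$id_a, .data$id_b)

  used_gene_a <- character(); used_gene_b <- character()
  used_id_a <- character(); used_id_b <- character()
  keep <- logical(nrow(x)); reason <- rep(NA_character_, nrow(x))
  for (i in seq_len(nrow(x))) {
    ga <- x$ref_gene_a[i]; gb <- x$ref_gene_b[i]
    if (x$id_a[i] %in% used_id_a || x$id_b[i] %in% used_id_b) {
      reason[i] <- "transcript_already_paired"
    } else if (!is.na(ga) && ga %in% used_gene_a) {
      reason[i] <- "isoform_of_retained_gene_species_a"
    } else if (!is.na(gb) && gb %in% used_gene_b) {
      reason[i] <- "isoform_of_retained_gene_species_b"
    } else {
      keep[i] <- TRUE
      used_id_a <- c(used_id_a, x$id_a[i])
      used_id_b <- c(used_id_b, x$id_b[i])
      if (!is.na(ga)) used_gene_a <- c(used_gene_a, ga)
      if (!is.na(gb)) used_gene_b <- c(used_gene_b, gb)
    }
  }
  kept <- x[keep, ]
  kept <- kept |>
    dplyr::mutate(
      naming_conflict = !is.na(.data$ref_gene_a) & !is.na(.data$ref_gene_b) &
        .data$ref_gene_a != .data$ref_gene_b,
      ref_gene = dplyr::coalesce(.data$ref_gene_a, .data$ref_gene_b)
    )
  n_unnamed <- sum(is.na(kept$ref_gene))
  kept$final_name <- kept$ref_gene
  kept$final_name[is.na(kept$final_name)] <- as.character(seq_len(n_unnamed))
  excluded <- dplyr::mutate(x[!keep, ], reason = reason[!keep])
  list(pairs = dplyr::select(kept, "final_name", dplyr::everything()),
       excluded = excluded)
}

#' Build the 1:1 ortholog-transcriptome from two assemblies
#'
#' End-to-end reciprocal-best-hit ortholog construction: cross-species
#' searches both ways, co-best sets, reciprocal pairs, the alignment-length
#' and length-ratio filters, reference-gene assignment and isoform pruning.
#'
#' @param tx_a,tx_b chimera-resolved transcript tibbles for species A and B.
#' @param reference reference gene set tibble (for naming), or `NULL` to
#'   skip reference assignment (pairs are then numbered).
#' @param min_align_len,min_length_ratio pair filters (see [filter_pairs()]).
#' @param word_size,max_evalue aligner settings passed to
#'   [seed_extend_align()].
#' @return list with `pairs` (final table), `excluded` (exclusion log across
#'   the filter and pruning stages) and the intermediate `candidates`.
#' @export
map_orthologs <- function(tx_a, tx_b, reference = NULL,
                          min_align_len = 250, min_length_ratio = 0.5,
                          word_size = 11, max_evalue = 1e-6) {
  hits_ab <- seed_extend_align(tx_a, tx_b, word_size = word_size,
                               max_evalue = max_evalue)
  hits_ba <- seed_extend_align(tx_b, tx_a, word_size = word_size,
                               max_evalue = max_evalue)
  candidates <- reciprocal_best_pairs(best_hit_sets(hits_ab),
                                      best_hit_sets(hits_ba))
  lengths <- c(transcript_lengths(tx_a), transcript_lengths(tx_b))
  flt <- filter_pairs(candidates, lengths, min_align_len = min_align_len,
                      min_length_ratio = min_length_ratio)
  if (!is.null(reference)) {
    ref_a <- assign_reference_gene(
      seed_extend_align(tx_a, reference, word_size = word_size,
                        max_evalue = max_evalue))
    ref_b <- assign_reference_gene(
      seed_extend_align(tx_b, reference, word_size = word_size,
                        max_evalue = max_evalue))
  } else {
    ref_a <- ref_b <- tibble::tibble(id = character(), ref_gene = character(),
                                     ref_subject = character(),
                                     ref_bitscore = numeric())
  }
  pruned <- prune_isoforms(flt$pairs, ref_a, ref_b)
  excluded <- dplyr::bind_rows(
    dplyr::select(flt$excluded, "id_a", "id_b", "align_len_ab", "reason"),
    dplyr::select(pruned$excluded, "id_a", "id_b", "align_len_ab", "reason")
  )
  list(pairs = pruned$pairs, excluded = excluded, candidates = candidates)
}
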