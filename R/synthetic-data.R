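#' Generate a reference gene set
#'
#' Simulates a reference cDNA collection playing the role of the annotated
#' gene-model set the assemblies are compared against. A fraction of genes
#' carry a second isoform derived from the first by an internal deletion or a
#' shortened 3' end, so isoforms of one gene stay >= 80% identical.
#'
#' @param n_genes number of genes (>= 1).
#' @param isoform_fraction proportion of genes carrying a second isoform.
#' @param length_range integer vector of length 2, sequence length bounds in
#'   nucleotides; must lie within \[200, 20000\].
#' @param seed integer seed; identical calls are byte-identical.
#' @return tibble with columns `id` (gene.isoform), `gene_id`, `isoform`,
#'   `sequence`, `length`.
#' @export
generate_reference_gene_set <- function(n_genes, isoform_fraction = 0,
                                        length_range = c(500, 2500),
                                        seed = 1L) {
  if (n_genes < 1) stop_config("n_genes must be >= 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 200 || length_range[2] > 20000)
    stop_config("length_range must be an increasing interval within [200, 20000]")
  if (isoform_fraction < 0 || isoform_fraction > 1)
    stop_config("isoform_fraction must be in [0, 1]")

  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    len <- sample(seq(length_range[1], length_range[2]), n_genes, replace = TRUE)
    seqs <- vapply(len, random_dna, character(1))
    base <- tibble::tibble(
      id = paste0(gene_id, ".1"), gene_id = gene_id, isoform = "1",
      sequence = seqs, length = len
    )
    n_iso <- round(isoform_fraction * n_genes)
    if (n_iso == 0) return(base)
    iso_genes <- sort(sample.int(n_genes, n_iso))
    iso <- purrr::map_dfr(iso_genes, function(i) {
      s <- seqs[i]
      L <- len[i]
      cut <- max(1L, round(L * runif(1, 0.10, 0.18)))
      if (runif(1) < 0.5 && L - cut >= 200) {
        # internal deletion
        start <- sample.int(L - cut, 1)
        s2 <- paste0(substr(s, 1, start), substr(s, start + cut + 1, L))
      } else {
        # alternative (shorter) 3' end
        s2 <- substr(s, 1, max(200L, L - cut))
      }
      tibble::tibble(id = paste0(gene_id[i], ".2"), gene_id = gene_id[i],
                     isoform = "2", sequence = s2, length = nchar(s2))
    })
    dplyr::arrange(dplyr::bind_rows(base, iso), .data$id)
  })
}

# Build one fused (chimeric) transcript from two already-mutated gene copies.
# "small": plain 5'-of-X + 3'-of-Y concatenation; the two reference hits abut
# on the fusion, so their overlap/gap is tiny (< 150 nt branch).
# "large": the junction region is a mosaic carrying diverged duplicated chunks
# of both source genes, the only honest way the two reference hits can overlap
# by >= 150 nt on the query without the references themselves being homologs.
build_fusion <- function(seq_x, seq_y, kind, chunk = 100L) {
  lx <- nchar(seq_x); ly <- nchar(seq_y)
  a <- round(lx * runif(1, 0.40, 0.60))
  b <- round(ly * runif(1, 0.40, 0.60))
  if (kind == "small") {
    list(sequence = paste0(substr(seq_x, 1, a), substr(seq_y, b + 1, ly)),
         junction = a)
  } else {
    chunk_y <- mutate_sequence(substr(seq_y, b - chunk + 1, b), 0.05)
    chunk_x <- mutate_sequence(substr(seq_x, lx - chunk + 1, lx), 0.05)
    list(sequence = paste0(substr(seq_x, 1, a), chunk_y, chunk_x,
                           substr(seq_y, b + 1, ly)),
         junction = a + chunk)
  }
}

#' Generate a diverged species pair with planted chimeras
#'
#' Each species' transcript set is an independently substitution-mutated copy
#' of every reference isoform, plus `n_chimeras` fused transcripts with
#' recorded junctions and optional truncated fragments. `overlap_mix` of the
#' fusions are plain concatenations whose two best reference hits abut (the
#' `< 150` nt overlap branch of the splitting rule); the rest carry a
#' duplicated mosaic junction so the two reference hits overlap by well over
#' 150 nt (the corrected-boundary branch).
#'
#' @param ref reference gene set from [generate_reference_gene_set()].
#' @param divergence per-site substitution rate in \[0, 0.1\] applied
#'   independently to each species.
#' @param n_chimeras fused transcripts planted per species (<= n_genes / 2).
#' @param overlap_mix proportion of fusions built with a < 150 nt hit overlap.
#' @param fragment_fraction proportion of non-chimeric transcripts truncated.
#' @param seed integer seed.
#' @return list with `species_a`, `species_b` (transcript tibbles with
#'   `is_chimera`/`is_fragment` flags) and `truth` (list with `chimera` and
#'   `ortholog` tibbles).
#' @export
generate_species_pair <- function(ref, divergence = 0.02, n_chimeras = 0,
                                  overlap_mix = 0.5, fragment_fraction = 0,
                                  seed = 1L) {
  if (divergence < 0 || divergence > 0.1)
    stop_config("divergence must be in [0, 0.1]")
  n_genes <- dplyr::n_distinct(ref$gene_id)
  if (n_chimeras > n_genes / 2)
    stop_config("n_chimeras must be <= n_genes / 2")

  with_seed(seed, {
    make_species <- function(prefix) {
      tx <- tibble::tibble(
        id = sprintf("%s_%05d", prefix, seq_len(nrow(ref))),
        source_id = ref$id,
        gene_id = ref$gene_id,
        sequence = vapply(ref$sequence, mutate_sequence, character(1),
                          rate = divergence, USE.NAMES = FALSE),
        is_chimera = FALSE,
        is_fragment = FALSE
      )
      chim_truth <- tibble::tibble(
        species = character(), transcript_id = character(),
        gene_5p = character(), gene_3p = character(),
        junction = integer(), overlap_class = character()
      )
      if (n_chimeras > 0) {
        eligible <- ref |>
          dplyr::filter(.data$isoform == "1", .data$length >= 900)
        if (nrow(eligible) < 2 * n_chimeras)
          stop_config("not enough genes >= 900 nt to plant the requested chimeras")
        picks <- matrix(sample(eligible$gene_id, 2 * n_chimeras), ncol = 2)
        n_small <- round(overlap_mix * n_chimeras)
        kinds <- c(rep("small", n_small), rep("large", n_chimeras - n_small))
        fused <- purrr::map_dfr(seq_len(n_chimeras), function(i) {
          gx <- picks[i, 1]; gy <- picks[i, 2]
          sx <- mutate_sequence(
            eligible$sequence[eligible$gene_id == gx], divergence)
          sy <- mutate_sequence(
            eligible$sequence[eligible$gene_id == gy], divergence)
          fus <- build_fusion(sx, sy, kinds[i])
          tibble::tibble(
            id = sprintf("%s_chim%04d", prefix, i), source_id = NA_character_,
            gene_id = NA_character_, sequence = fus$sequence,
            is_chimera = TRUE, is_fragment = FALSE,
            gene_5p = gx, gene_3p = gy, junction = as.integer(fus$junction),
            overlap_class = kinds[i]
          )
        })
        chim_truth <- fused |>
          dplyr::transmute(species = prefix, transcript_id = .data$id,
                           .data$gene_5p, .data$gene_3p, .data$junction,
                           .data$overlap_class)
        tx <- dplyr::bind_rows(
          tx, dplyr::select(fused, -"gene_5p", -"gene_3p", -"junction",
                            -"overlap_class"))
      }
      if (fragment_fraction > 0) {
        idx <- which(!tx$is_chimera)
        n_frag <- round(fragment_fraction * length(idx))
        if (n_frag > 0) {
          fr <- sample(idx, n_frag)
          tx$sequence[fr] <- vapply(tx$sequence[fr], function(s) {
            keep <- max(250L, round(nchar(s) * runif(1, 0.4, 0.8)))
            substr(s, 1, min(keep, nchar(s)))
          }, character(1), USE.NAMES = FALSE)
          tx$is_fragment[fr] <- TRUE
        }
      }
      tx$length <- nchar(tx$sequence)
      list(tx = tx, chim = chim_truth)
    }

    a <- make_species("A")
    b <- make_species("B")
    ortholog_truth <- ref |>
      dplyr::distinct(.data$gene_id) |>
      dplyr::mutate(
        ids_a = purrr::map(.data$gene_id, function(g)
          a$tx$id[!is.na(a$tx$gene_id) & a$tx$gene_id == g]),
        ids_b = purrr::map(.data$gene_id, function(g)
          b$tx$id[!is.na(b$tx$gene_id) & b$tx$gene_id == g])
      )
    list(
      species_a = a$tx, species_b = b$tx,
      truth = list(chimera = dplyr::bind_rows(a$chim, b$chim),
                   ortholog = ortholog_truth)
    )
  })
}

#' Generate a negative-binomial count experiment with planted effects
#'
#' Emulates the 18-sample layout of two species (A dehiscent-like, B
#' indehiscent-like) by three structures (bud, flower, fruit) with three
#' replicates, under the model `~ species + structure + species:structure`
#' with a log length offset for transcript features. `ddeg_fraction` of
#' features receive nonzero interaction coefficients (magnitude
#' `effect_size_log2`, random signs, one per structure transition);
#' `deg_fraction` receive a species main-effect shift only.
#'
#' @param features number of features.
#' @param n_reps replicates per species x structure cell.
#' @param baseline_mean_log2 numeric length 2, mean and sd of the log2
#'   baseline expression across features.
#' @param baseline_min lower bound for baseline means on the count scale.
#' @param dispersion NB dispersion alpha (> 0 for overdispersed counts; 0
#'   draws Poisson counts).
#' @param deg_fraction,ddeg_fraction proportions of features with planted
#'   main-effect and interaction effects (disjoint sets).
#' @param effect_size_log2 magnitude of planted effects on the log2 scale.
#' @param feature_lengths optional vector of feature lengths (nt); sampled
#'   in 300-3000 if `NULL` and `feature_kind == "transcript"`.
#' @param feature_kind "transcript" (length offsets) or "mirna" (no offsets).
#' @param seed integer seed.
#' @return list with `experiment` (a [count_experiment()]) and `truth`
#'   (tibble of per-feature planted coefficients, flags and dispersion).
#' @export
generate_count_experiment <- function(features = 2000, n_reps = 3,
                                      baseline_mean_log2 = c(7, 1.5),
                                      baseline_min = 1,
                                      dispersion = 0.1,
                                      deg_fraction = 0, ddeg_fraction = 0,
                                      effect_size_log2 = 2,
                                      feature_lengths = NULL,
                                      feature_kind = c("transcript", "mirna"),
                                      seed = 1L) {
  feature_kind <- match.arg(feature_kind)
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  for (f in c(deg_fraction, ddeg_fraction))
    if (f < 0 || f > 1) stop_config("fractions must be in [0, 1]")

  with_seed(seed, {
    samples <- tidyr::expand_grid(
      species = c("A", "B"), structure = c("bud", "flower", "fruit"),
      replicate = seq_len(n_reps)
    ) |>
      dplyr::mutate(sample = paste(.data$species, .data$structure,
                                   .data$replicate, sep = "_"),
                    .before = 1)
    X <- design_matrix(samples)
    n <- nrow(samples)

    fid <- sprintf("f%05d", seq_len(features))
    b0 <- pmax(rnorm(features, baseline_mean_log2[1], baseline_mean_log2[2]),
               log2(baseline_min))
    beta <- matrix(0, features, 6,
                   dimnames = list(fid, colnames(X)))
    beta[, 1] <- b0

    n_ddeg <- round(ddeg_fraction * features)
    n_deg <- round(deg_fraction * features)
    idx <- sample.int(features, n_ddeg + n_deg)
    ddeg_idx <- idx[seq_len(n_ddeg)]
    deg_idx <- setdiff(idx, ddeg_idx)
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    if (n_ddeg > 0) {
      beta[ddeg_idx, 5] <- sgn(n_ddeg) * effect_size_log2
      beta[ddeg_idx, 6] <- sgn(n_ddeg) * effect_size_log2
    }
    if (n_deg > 0) beta[deg_idx, 2] <- sgn(n_deg) * effect_size_log2

    if (feature_kind == "transcript") {
      if (is.null(feature_lengths))
        feature_lengths <- sample(300:3000, features, replace = TRUE)
      if (length(feature_lengths) != features)
        stop_config("feature_lengths must have one entry per feature")
      offset <- log(feature_lengths / 1000)
    } else {
      feature_lengths <- NULL
      offset <- rep(0, features)
    }

    mu <- exp(log(2) * (beta %*% t(X)) + offset)  # features x samples
    counts <- matrix(
      if (dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else rpois(length(mu), lambda = mu),
      nrow = features, dimnames = list(fid, samples$sample)
    )

    truth <- tibble::tibble(
      feature_id = fid,
      baseline_log2 = b0,
      beta_species = beta[, 2],
      beta_flower = beta[, 3], beta_fruit = beta[, 4],
      beta_int_flower = beta[, 5], beta_int_fruit = beta[, 6],
      is_deg = seq_len(features) %in% deg_idx,
      is_ddeg = seq_len(features) %in% ddeg_idx,
      dispersion = dispersion
    )
    lengths <- if (is.null(feature_lengths)) NULL else
      setNames(feature_lengths, fid)
    list(
      experiment = count_experiment(counts, samples, lengths = lengths,
                                    kind = feature_kind),
      truth = truth
    )
  })
}

#' Generate small-RNA reads from a mature miRNA reference
#'
#' Emulates trimmed 18-26 nt small-RNA libraries: each read is one mature
#' sequence carrying 0 or 1 random substitutions (one with probability
#' `mismatch_rate`), with per-sample read counts Poisson around the given
#' abundances.
#'
#' @param mirna_ref tibble with `name` and `sequence` (18-26 nt, ACGT/U).
#' @param abundance expected reads per mature sequence: numeric vector
#'   (recycled over samples) or matrix (miRNAs x samples).
#' @param n_samples number of samples when `abundance` is a vector.
#' @param mismatch_rate per-read probability of carrying one substitution.
#' @param seed integer seed.
#' @return list with `reads` (tibble: sample, read_id, sequence, source) and
#'   `truth` (tibble: name, sample, planted_count).
#' @export
generate_small_rna_reads <- function(mirna_ref, abundance, n_samples = 3,
                                     mismatch_rate = 0.1, seed = 1L) {
  seqs <- toupper(gsub("U", "T", mirna_ref$sequence))
  wid <- nchar(seqs)
  if (any(wid < 18 | wid > 26))
    stop_config("mature sequences must be 18-26 nt")
  if (mismatch_rate < 0 || mismatch_rate > 1)
    stop_config("mismatch_rate must be in [0, 1]")
  if (is.matrix(abundance)) {
    n_samples <- ncol(abundance)
  } else {
    abundance <- matrix(rep(rep_len(abundance, nrow(mirna_ref)), n_samples),
                        ncol = n_samples)
  }
  if (nrow(abundance) != nrow(mirna_ref))
    stop_config("abundance must have one row per mature sequence")

  with_seed(seed, {
    out <- list(); truth <- list()
    for (s in seq_len(n_samples)) {
      counts <- rpois(nrow(mirna_ref), abundance[, s])
      src <- rep(mirna_ref$name, counts)
      rs <- rep(seqs, counts)
      mut <- runif(length(rs)) < mismatch_rate
      rs[mut] <- vapply(rs[mut], function(x) {
        p <- sample.int(nchar(x), 1)
        substr(x, p, p) <- sample(setdiff(DNA_BASES, substr(x, p, p)), 1)
        x
      }, character(1), USE.NAMES = FALSE)
      sample_id <- sprintf("s%02d", s)
      out[[s]] <- tibble::tibble(
        sample = sample_id,
        read_id = sprintf("%s_r%06d", sample_id, seq_along(rs)),
        sequence = rs, source = src
      )
      truth[[s]] <- tibble::tibble(sample = sample_id, name = mirna_ref$name,
                                   planted_count = counts)
    }
    list(reads = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
  })
}
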