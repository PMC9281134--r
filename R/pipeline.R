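#' Pipeline configuration
#'
#' Centralizes every numeric threshold of the pipeline. Defaults are the
#' study's stated constants (150 nt chimera overlap, > 250 nt pair alignment,
#' 50% length ratio, < 19 low-count filter, |log2FC| > 1, alpha = 0.001,
#' 18-26 nt small-RNA reads, 1 miRNA mismatch); the synthetic-run sizes are
#' desk-scale choices documented in the methods vignette.
#'
#' @param ... overrides of the default keys; unknown keys are errors.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    config_version = 1,
    # splitting / orthology thresholds
    chimera_overlap = 150, min_pair_align = 250, min_length_ratio = 0.5,
    chimera_min_interval = 100, chimera_max_overlap_frac = 0.5,
    # expression thresholds
    low_count = 19, lfc_threshold = 1, alpha = 0.001,
    # miRNA contract
    mirna_read_len_min = 18, mirna_read_len_max = 26, mirna_mismatch = 1,
    # aligner
    word_size = 11, max_evalue = 1e-6,
    # synthetic demo scale
    n_genes = 250, isoform_fraction = 0.15, divergence = 0.02,
    n_chimeras = 12, overlap_mix = 0.5, fragment_fraction = 0.05,
    n_features = 1200, dispersion = 0.1, deg_fraction = 0.1,
    ddeg_fraction = 0.05, effect_size_log2 = 2,
    n_mirnas = 40, mirna_abundance = 80, mirna_mismatch_rate = 0.1,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_config <- function(cfg) {
  pos <- c("chimera_overlap", "min_pair_align", "min_length_ratio",
           "low_count", "lfc_threshold", "mirna_read_len_min",
           "mirna_read_len_max", "word_size")
  for (k in pos) if (cfg[[k]] <= 0) stop_config(paste0(k, " must be positive"))
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_config("alpha must be in (0, 1)")
  invisible(cfg)
}

#' Write / read a flat key-value pipeline configuration
#'
#' Plain `key = value` text with a versioned schema; unknown keys are errors
#' on read (silent threshold typos are the main reproducibility hazard).
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return the path (write) or a `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], scientific = FALSE)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(x[2]))
    if (is.na(v)) x[2] else v
  })
  do.call(pipeline_config, setNames(vals, trimws(keys)))
}

config_hash <- function(cfg) {
  fnv1a_hash(vapply(names(cfg), function(k)
    paste0(k, "=", format(cfg[[k]], digits = 15)), character(1)))
}

log_line <- function(log_path, msg) {
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the pipeline end-to-end on synthetic data
#'
#' Executes the stages in order — simulate, chimera resolution (both
#' species), ortholog mapping, miRNA cataloging, differential expression,
#' enrichment, report — writing every stage's outputs plus a manifest
#' carrying the config hash and seed. Reruns with identical config are
#' byte-identical (the log file carries no timestamps either).
#'
#' With `entry_stage = "de"` only the expression stages run, on a count
#' matrix supplied via `inputs` (paths `counts`, `samples`, optionally
#' `lengths`).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory, created if needed.
#' @param entry_stage `"simulate"` (full synthetic run) or `"de"`.
#' @param inputs named list of input paths for later entry stages.
#' @return invisibly, a list of the main stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         entry_stage = c("simulate", "de"), inputs = NULL) {
  entry_stage <- match.arg(entry_stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  log_line(log_path, sprintf("run config_hash=%s seed=%d entry=%s",
                             hash, seed, entry_stage))
  write_config(config, file.path(outdir, "config.txt"))

  results <- list()

  if (entry_stage == "simulate") {
    # --- simulate -----------------------------------------------------------
    ref <- generate_reference_gene_set(config$n_genes,
                                       isoform_fraction = config$isoform_fraction,
                                       seed = seed)
    pair <- generate_species_pair(ref, divergence = config$divergence,
                                  n_chimeras = config$n_chimeras,
                                  overlap_mix = config$overlap_mix,
                                  fragment_fraction = config$fragment_fraction,
                                  seed = seed + 1)
    write_transcript_fasta(ref, file.path(outdir, "reference.fasta"))
    write_transcript_fasta(pair$species_a, file.path(outdir, "species_a.fasta"))
    write_transcript_fasta(pair$species_b, file.path(outdir, "species_b.fasta"))
    readr::write_tsv(pair$truth$chimera,
                     file.path(outdir, "truth_chimera.tsv"))
    log_line(log_path, sprintf(
      "simulate: %d reference sequences, %d + %d transcripts, %d planted chimeras",
      nrow(ref), nrow(pair$species_a), nrow(pair$species_b),
      nrow(pair$truth$chimera)))

    # --- chimera resolution -------------------------------------------------
    ref_lengths <- transcript_lengths(ref)
    resolve_one <- function(tx, label) {
      hits <- seed_extend_align(tx, ref, word_size = config$word_size,
                                max_evalue = config$max_evalue)
      write_hit_table(hits, file.path(outdir, paste0("hits_", label,
                                                     "_vs_ref.tsv")))
      res <- resolve_assembly(tx, hits, ref_lengths,
                              overlap_threshold = config$chimera_overlap,
                              min_interval = config$chimera_min_interval,
                              max_overlap_frac = config$chimera_max_overlap_frac)
      write_transcript_fasta(res$transcripts,
                             file.path(outdir, paste0(label, "_resolved.fasta")))
      readr::write_tsv(res$report,
                       file.path(outdir, paste0("chimera_report_", label,
                                                ".tsv")))
      log_line(log_path, sprintf(
        "chimera[%s]: %d transcripts in, %d calls, %d transcripts out",
        label, nrow(tx), nrow(res$report), nrow(res$transcripts)))
      res
    }
    res_a <- resolve_one(pair$species_a, "species_a")
    res_b <- resolve_one(pair$species_b, "species_b")
    results$chimera <- list(a = res_a, b = res_b)

    # --- orthologs ----------------------------------------------------------
    orth <- map_orthologs(res_a$transcripts, res_b$transcripts, ref,
                          min_align_len = config$min_pair_align,
                          min_length_ratio = config$min_length_ratio,
                          word_size = config$word_size,
                          max_evalue = config$max_evalue)
    readr::write_tsv(orth$pairs, file.path(outdir, "ortholog_pairs.tsv"))
    readr::write_tsv(orth$excluded, file.path(outdir, "ortholog_excluded.tsv"))
    log_line(log_path, sprintf(
      "orthologs: %d candidates, %d final 1:1 pairs, %d excluded",
      nrow(orth$candidates), nrow(orth$pairs), nrow(orth$excluded)))
    results$orthologs <- orth

    # --- miRNA stage --------------------------------------------------------
    mir <- with_seed(seed + 2, {
      mature <- tibble::tibble(
        name = sprintf("mir%03d", seq_len(config$n_mirnas)),
        sequence = vapply(sample(20:22, config$n_mirnas, replace = TRUE),
                          random_dna, character(1))
      )
      groups <- collapse_mature_mirnas(mature)
      reads_a <- generate_small_rna_reads(mature, config$mirna_abundance,
                                          mismatch_rate = config$mirna_mismatch_rate,
                                          seed = seed + 3)
      reads_b <- generate_small_rna_reads(mature, config$mirna_abundance,
                                          mismatch_rate = config$mirna_mismatch_rate,
                                          seed = seed + 4)
      cnt_a <- match_reads_to_groups(reads_a$reads, groups,
                                     max_mismatch = config$mirna_mismatch)
      cnt_b <- match_reads_to_groups(reads_b$reads, groups,
                                     max_mismatch = config$mirna_mismatch)
      list(groups = groups, counts_a = cnt_a, counts_b = cnt_b,
           orthologs = mirna_orthologs(cnt_a$presence, cnt_b$presence))
    })
    readr::write_tsv(dplyr::select(mir$groups, "group_id", "n_members"),
                     file.path(outdir, "mirna_groups.tsv"))
    readr::write_tsv(mir$counts_a$counts,
                     file.path(outdir, "mirna_counts_species_a.tsv"))
    readr::write_tsv(mir$counts_b$counts,
                     file.path(outdir, "mirna_counts_species_b.tsv"))
    writeLines(mir$orthologs, file.path(outdir, "mirna_orthologs.txt"))
    log_line(log_path, sprintf(
      "mirna: %d groups, %d ortholog groups", nrow(mir$groups),
      length(mir$orthologs)))
    results$mirna <- mir

    # --- counts on the ortholog features ------------------------------------
    n_feat <- nrow(orth$pairs)
    pair_lengths <- pmin(orth$pairs$len_a, orth$pairs$len_b)
    sim <- generate_count_experiment(
      features = n_feat, dispersion = config$dispersion,
      deg_fraction = config$deg_fraction, ddeg_fraction = config$ddeg_fraction,
      effect_size_log2 = config$effect_size_log2,
      feature_lengths = pair_lengths, seed = seed + 5)
    # identify count features with the ortholog pairs
    fid <- orth$pairs$final_name
    rownames(sim$experiment$counts) <- fid
    names(sim$experiment$lengths) <- fid
    sim$truth$feature_id <- fid
    experiment <- sim$experiment
    truth <- sim$truth
    readr::write_tsv(truth, file.path(outdir, "truth_counts.tsv"))
    write_count_experiment(experiment,
                           file.path(outdir, "counts.tsv"),
                           file.path(outdir, "samples.tsv"),
                           file.path(outdir, "feature_lengths.tsv"))
    log_line(log_path, sprintf("counts: %d features x %d samples",
                               nrow(experiment$counts),
                               ncol(experiment$counts)))
  } else {
    if (is.null(inputs$counts) || is.null(inputs$samples))
      stop_config("entry_stage 'de' needs inputs$counts and inputs$samples")
    experiment <- read_count_experiment(inputs$counts, inputs$samples,
                                        inputs$lengths)
    log_line(log_path, sprintf("ingest: %d features x %d samples",
                               nrow(experiment$counts),
                               ncol(experiment$counts)))
  }

  # --- differential expression ---------------------------------------------
  de <- run_de_analysis(experiment, alpha = config$alpha,
                        lfc = config$lfc_threshold,
                        low_count = config$low_count)
  readr::write_tsv(de$tests, file.path(outdir, "de_tests.tsv"))
  readr::write_tsv(de$calls, file.path(outdir, "de_calls.tsv"))
  log_line(log_path, sprintf("de: %d features tested, %d consensus calls",
                             nrow(de$experiment$counts), sum(de$calls$called)))
  results$de <- de

  pca <- pca_profile(de$normalized, de$experiment$samples)
  readr::write_tsv(pca, file.path(outdir, "pca_coordinates.tsv"))

  # --- enrichment -----------------------------------------------------------
  universe <- rownames(de$experiment$counts)
  term_map <- with_seed(seed + 6, tibble::tibble(
    term = sample(sprintf("TERM%03d", 1:20), 4 * length(universe),
                  replace = TRUE),
    feature_id = rep(universe, 4)
  ))
  ddeg <- de$calls |>
    dplyr::filter(.data$test == "interaction", .data$called) |>
    dplyr::pull(.data$feature_id)
  enr <- if (length(ddeg) > 0)
    fisher_enrichment(ddeg, universe, term_map) else
    fisher_enrichment(character(0), universe, term_map)
  readr::write_tsv(enr, file.path(outdir, "enrichment_interaction.tsv"))
  log_line(log_path, sprintf("enrich: %d terms tested on %d DDEGs",
                             nrow(enr), length(ddeg)))
  results$enrichment <- enr

  # --- report + manifest ----------------------------------------------------
  write_report(outdir, de)
  manifest <- c(
    sprintf("config_hash: %s", hash),
    sprintf("seed: %d", seed),
    sprintf("entry_stage: %s", entry_stage),
    sprintf("outputs: %s", paste(sort(setdiff(list.files(outdir),
                                              c("manifest.txt", "run.log"))),
                                 collapse = " "))
  )
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  log_line(log_path, "done")
  invisible(results)
}

#' Write the human-readable run report
#'
#' Summarizes consensus DEG counts per comparison (up/down split) and the
#' DDEG (interaction) count, as a TSV plus a plain-text summary.
#'
#' @param outdir run directory.
#' @param de a `de_result`; read from the run directory's `de_calls.tsv`
#'   when missing.
#' @return invisibly, the summary tibble.
#' @export
write_report <- function(outdir, de = NULL) {
  calls <- if (!is.null(de)) de$calls else {
    path <- file.path(outdir, "de_calls.tsv")
    if (!file.exists(path)) stop_validation("no de_calls.tsv in run directory")
    readr::read_tsv(path, show_col_types = FALSE)
  }
  summ <- calls |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_called = sum(.data$called),
      n_up = sum(.data$called & .data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$called & .data$direction == "down", na.rm = TRUE),
      .groups = "drop"
    )
  readr::write_tsv(summ, file.path(outdir, "call_summary.tsv"))
  lines <- c(
    "Differential expression call summary (consensus of both engines)",
    "",
    sprintf("%-28s %8s %8s %6s %6s", "comparison", "tested", "called",
            "up", "down"),
    vapply(seq_len(nrow(summ)), function(i) {
      lab <- if (summ$test[i] == "interaction") "interaction (DDEG)"
             else summ$test[i]
      sprintf("%-28s %8d %8d %6d %6d", lab, summ$n_tested[i],
              summ$n_called[i], summ$n_up[i], summ$n_down[i])
    }, character(1))
  )
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(summ)
}
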