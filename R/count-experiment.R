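#' Construct a count experiment
#'
#' Bundles a features x samples count matrix with sample metadata and optional
#' feature lengths, for the two-species x three-structure design.
#'
#' @param counts integer matrix (features x samples) with row and column
#'   names, or a tibble whose first column is the feature id.
#' @param samples tibble with columns `sample`, `species` (A/B), `structure`
#'   (bud/flower/fruit) and `replicate`; `sample` must match the count
#'   matrix columns.
#' @param lengths named numeric vector of feature lengths in nt (transcripts)
#'   or `NULL` (miRNAs).
#' @param kind `"transcript"` or `"mirna"`; miRNA features never receive
#'   length offsets.
#' @return object of class `count_experiment`.
#' @export
count_experiment <- function(counts, samples,
                             lengths = NULL,
                             kind = c("transcript", "mirna")) {
  kind <- match.arg(kind)
  if (is.data.frame(counts)) {
    fid <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- fid
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop_validation("counts must carry feature row names and sample column names")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_validation("counts must be finite and non-negative")
  need <- c("sample", "species", "structure", "replicate")
  if (!all(need %in% names(samples)))
    stop_validation("samples needs columns sample, species, structure, replicate")
  if (!setequal(samples$sample, colnames(counts)))
    stop_validation("sample metadata does not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (!all(samples$species %in% c("A", "B")))
    stop_validation("species must be coded A and B")
  if (!all(samples$structure %in% c("bud", "flower", "fruit")))
    stop_validation("structure must be one of bud, flower, fruit")
  cells <- dplyr::count(samples, .data$species, .data$structure)
  if (any(cells$n < 2))
    stop_validation("every species x structure cell needs >= 2 replicates")
  if (!is.null(lengths)) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss) > 0)
      stop_validation(paste0("missing feature lengths for: ",
                             paste(head(miss, 3), collapse = ", ")))
    lengths <- lengths[rownames(counts)]
  }
  structure(
    list(counts = counts, samples = tibble::as_tibble(samples),
         lengths = lengths, kind = kind),
    class = "count_experiment"
  )
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("<count_experiment> %d %s features x %d samples\n",
              nrow(x$counts), x$kind, ncol(x$counts)))
  cat(sprintf("  design cells: %s\n",
              paste(with(x$samples, paste0(species, ":", structure)) |>
                      unique() |> sort(), collapse = " ")))
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

#' Long-format view of a count experiment
#'
#' @param x a [count_experiment()].
#' @param ... unused.
#' @return tibble with one row per feature x sample, joined to the sample
#'   metadata.
#' @method tidy count_experiment
#' @export
tidy.count_experiment <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample",
                        values_to = "count") |>
    dplyr::left_join(x$samples, by = "sample")
}

# Full-rank design matrix for ~ species + structure + species:structure with
# reference levels species A and structure bud (6 columns for the 18-sample
# layout).
design_matrix <- function(samples, reduced = FALSE) {
  df <- data.frame(
    species = factor(samples$species, levels = c("A", "B")),
    structure = factor(samples$structure, levels = c("bud", "flower", "fruit"))
  )
  f <- if (reduced) ~ species + structure else
    ~ species + structure + species:structure
  X <- model.matrix(f, df)
  rownames(X) <- samples$sample
  X
}

#' Read a count experiment from TSV files
#'
#' @param counts_path TSV of counts, first column the feature id.
#' @param samples_path TSV with sample, species, structure, replicate.
#' @param lengths_path optional two-column TSV (feature_id, length).
#' @inheritParams count_experiment
#' @return a [count_experiment()].
#' @export
read_count_experiment <- function(counts_path, samples_path,
                                  lengths_path = NULL,
                                  kind = c("transcript", "mirna")) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- readr::read_tsv(lengths_path, show_col_types = FALSE)
    lengths <- setNames(lt[[2]], lt[[1]])
  }
  count_experiment(counts, samples, lengths = lengths, kind = match.arg(kind))
}

#' Write a count experiment to TSV files
#'
#' @param x a [count_experiment()].
#' @param counts_path,samples_path,lengths_path output paths; lengths are
#'   only written when present and a path is given.
#' @return invisibly, the counts path.
#' @export
write_count_experiment <- function(x, counts_path, samples_path,
                                   lengths_path = NULL) {
  readr::write_tsv(tibble::as_tibble(x$counts, rownames = "feature_id"),
                   counts_path)
  readr::write_tsv(x$samples, samples_path)
  if (!is.null(lengths_path) && !is.null(x$lengths))
    readr::write_tsv(tibble::tibble(feature_id = names(x$lengths),
                                    length = unname(x$lengths)),
                     lengths_path)
  invisible(counts_path)
}
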