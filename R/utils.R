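DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitution-only mutation at a fixed per-site rate. Indel-free by design so
# planted junction coordinates stay exact.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Hamming distance between equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(charToRaw(a) != charToRaw(b))
}

# FNV-1a hash of a character scalar, as 8 hex digits. Used for config
# provenance stamps; not cryptographic.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep the arithmetic inside
    # double precision by multiplying 16-bit halves separately
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Scoped RNG: run code under a seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# gene id of a reference transcript id: strip a trailing ".<digits>" isoform
# suffix (TAIR-style AT1G01010.1 -> AT1G01010, synthetic g0001.2 -> g0001).
infer_gene_id <- function(ids) {
  sub("\\.\\d+$", "", ids)
}

stop_config <- function(msg) {
  rlang::abort(msg, class = "orthode_config_error")
}

stop_validation <- function(msg) {
  rlang::abort(msg, class = "orthode_validation_error")
}
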