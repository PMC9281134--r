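# Shared small fixtures, built in code.

# one alignment-hit row with sensible defaults
hit_row <- function(query_id = "q1", subject_id = "s1", pct_identity = 100,
                    align_len = 100L, mismatches = 0L, gap_opens = 0L,
                    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
                    evalue = 1e-50, bitscore = 200) {
  tibble::tibble(query_id, subject_id, pct_identity,
                 align_len = as.integer(align_len),
                 mismatches = as.integer(mismatches),
                 gap_opens = as.integer(gap_opens),
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 s_start = as.integer(s_start), s_end = as.integer(s_end),
                 evalue, bitscore)
}

# fixed-seed random DNA string
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k positions of a sequence (guaranteed base change)
substitute_at <- function(seq, pos) {
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  seq
}

# minimal 18-sample metadata (2 species x 3 structures x 3 reps)
toy_samples <- function() {
  tidyr::expand_grid(species = c("A", "B"),
                     structure = c("bud", "flower", "fruit"),
                     replicate = 1:3) |>
    dplyr::mutate(sample = paste(species, structure, replicate, sep = "_"),
                  .before = 1)
}

# small count experiment with given matrix-free counts
toy_experiment <- function(counts, lengths = NULL, kind = "transcript") {
  count_experiment(counts, toy_samples(), lengths = lengths, kind = kind)
}

# independent NB log-likelihood oracle via dnbinom (alpha = 1/size)
nb_loglik_oracle <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# brute-force zooming grid search over a 2-coefficient NB GLM log-likelihood
grid_oracle_loglik <- function(y, X, offset, alpha, center, span = 2,
                               rounds = 4, k = 41) {
  best <- -Inf
  b <- center
  for (r in seq_len(rounds)) {
    g1 <- seq(b[1] - span, b[1] + span, length.out = k)
    g2 <- seq(b[2] - span, b[2] + span, length.out = k)
    for (b1 in g1) for (b2 in g2) {
      mu <- exp(X %*% c(b1, b2) + offset)
      ll <- nb_loglik_oracle(y, mu, alpha)
      if (ll > best) { best <- ll; b <- c(b1, b2) }
    }
    span <- span / 10
  }
  best
}

# brute-force transitive closure of the <=1-mismatch relation (miRNA oracle)
hamming_closure_oracle <- function(seqs) {
  seqs <- toupper(gsub("U", "T", seqs))
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- nchar(seqs[i]) == nchar(seqs[j]) &&
      sum(charToRaw(seqs[i]) != charToRaw(seqs[j])) <= 1
  }
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# two-sided Fisher p by hypergeometric enumeration on a 2x2 table
fisher_enum_oracle <- function(a, K, ts, N) {
  lo <- max(0, K + ts - N); hi <- min(K, ts)
  probs <- dhyper(lo:hi, ts, N - ts, K)
  p_obs <- dhyper(a, ts, N - ts, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
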