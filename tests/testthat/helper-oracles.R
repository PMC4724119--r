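# Independent oracles, deliberately sharing no code with the package:
# plain string scanning and explicit loops.

BASES4 <- c("A", "C", "G", "T")
PAIRS16 <- as.vector(t(outer(BASES4, BASES4, paste0)))

# Brute-force association scores by direct re-counting over the strings.
brute_scores <- function(seqs, procedure, pseudo = 0.001) {
  n_seq <- length(seqs)
  l <- nchar(seqs[1])
  out <- matrix(NA_real_, 16, l - 1, dimnames = list(PAIRS16, NULL))
  prob_at <- function(base, j) {
    hits <- 0
    for (s in seqs) if (substr(s, j, j) == base) hits <- hits + 1
    hits / n_seq
  }
  for (j in seq_len(l - 1)) {
    for (r in seq_len(16)) {
      b1 <- substr(PAIRS16[r], 1, 1)
      b2 <- substr(PAIRS16[r], 2, 2)
      n_obs <- 0
      for (s in seqs) {
        if (substr(s, j, j + 1) == paste0(b1, b2)) n_obs <- n_obs + 1
      }
      e <- n_seq * prob_at(b1, j) * prob_at(b2, j + 1)
      out[r, j] <- switch(procedure,
        "P-1" = log2((n_obs + pseudo) / (n_seq * 0.0625)),
        "P-2" = log2((n_obs + pseudo) / (e + pseudo)),
        "P-3" = log2((abs(n_obs - e) + pseudo) / (e + pseudo)))
    }
  }
  out
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to the two groups (tie-free data only).
mw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  idx_sets <- utils::combn(n + m, n)
  total <- ncol(idx_sets)
  u_all <- apply(idx_sets, 2, function(ix) {
    ga <- pooled[ix]; gb <- pooled[-ix]
    sum(outer(ga, gb, ">"))
  })
  p_lo <- sum(u_all <= u_obs) / total
  p_hi <- sum(u_all >= u_obs) / total
  min(1, 2 * min(p_lo, p_hi))
}

# Random A/C/G/T alignment of n sequences of length l.
random_alignment <- function(n, l, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(BASES4, l, replace = TRUE), collapse = "")
  }, character(1))
}
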