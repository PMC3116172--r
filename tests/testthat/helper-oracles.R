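# Independent oracle implementations, deliberately written as plain loops
# with no code shared with the package internals.

# Exhaustive greedy max-min ranking: recompute all pairwise distances and
# the arg-max of min-distance at every step; ties to the lowest index.
maxmin_oracle <- function(X, start = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  ranked <- start
  while (length(ranked) < n) {
    best <- NA_integer_; bestd <- -Inf
    for (i in seq_len(n)) {
      if (i %in% ranked) next
      mind <- Inf
      for (j in ranked) mind <- min(mind, D[i, j])
      if (mind > bestd) { bestd <- mind; best <- i }
    }
    ranked <- c(ranked, best)
  }
  as.integer(ranked)
}

# Brute-force naive-Bayes posterior with smoothed histograms: direct
# probability products, no logs, explicit double-loop smoothing.
naive_bayes_oracle <- function(Xtr, labels, xq, bins = 25L, sigma = 0.25,
                               prob_floor = 1e-9) {
  p <- ncol(Xtr)
  centers <- (seq_len(bins) - 0.5) / bins
  lik <- function(cls, j) {
    vals <- Xtr[labels == cls, j]
    lo <- min(Xtr[, j]); hi <- max(Xtr[, j])
    h <- rep(0, bins)
    if (hi > lo) {
      for (v in vals) {
        z <- (v - lo) / (hi - lo)
        b <- floor(z * bins) + 1L
        if (b > bins) b <- bins
        if (b < 1L) b <- 1L
        h[b] <- h[b] + 1
      }
    } else h <- rep(1, bins)
    sm <- rep(0, bins)
    for (b in seq_len(bins))
      for (b2 in seq_len(bins))
        sm[b] <- sm[b] + exp(-(centers[b] - centers[b2])^2 / (2 * sigma^2)) * h[b2]
    sm <- sm + prob_floor
    sm / sum(sm)
  }
  pa <- mean(labels); pi <- 1 - pa
  num_a <- pa; num_i <- pi
  for (j in seq_len(p)) {
    lo <- min(Xtr[, j]); hi <- max(Xtr[, j])
    z <- if (hi > lo) (xq[j] - lo) / (hi - lo) else 0.5
    if (z < 0) z <- 0
    if (z > 1) z <- 1
    b <- floor(z * bins) + 1L
    if (b > bins) b <- bins
    num_a <- num_a * lik(TRUE, j)[b]
    num_i <- num_i * lik(FALSE, j)[b]
  }
  num_a / (num_a + num_i)
}

# Closed-form two-sided paired t-test.
paired_t_oracle <- function(x, y) {
  d <- y - x
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, n = n)
}

# Brute-force unique single-point chimera count over toy R-group maps.
# inputs: list of character vectors (position -> group name), one scaffold.
chimera_count_oracle <- function(input_maps) {
  positions <- names(input_maps[[1]])
  observed <- lapply(positions, function(p)
    unique(vapply(input_maps, `[[`, "", p)))
  names(observed) <- positions
  seen_inputs <- vapply(input_maps, paste, "", collapse = "|")
  out <- character()
  for (m in input_maps)
    for (p in positions)
      for (g in observed[[p]]) {
        if (g == m[[p]]) next
        cand <- m; cand[[p]] <- g
        sig <- paste(cand, collapse = "|")
        if (!(sig %in% seen_inputs)) out <- c(out, sig)
      }
  length(unique(out))
}
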