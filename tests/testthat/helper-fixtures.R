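# Shared fixtures, built in code.

# A clean/polluted pair of hand-checkable sites.
toy_sites <- function() {
  data.frame(
    site_id = c("clean", "dirty"),
    reach = c("main", "tributary"),
    section = c("upstream", "downstream"),
    DO = c(9.0, 5.0),
    TN = c(0.1, 4.0),
    NH3N = c(0.05, 1.8),
    TP = c(0.008, 0.18),
    CODMn = c(0.5, 4.8),
    stringsAsFactors = FALSE
  )
}

# Random non-negative measurement matrix with the canonical columns.
random_matrix <- function(n, seed) {
  set.seed(seed)
  m <- cbind(
    DO = runif(n, 4, 12),
    TN = rlnorm(n, 0, 1),
    NH3N = rlnorm(n, -1.5, 1),
    TP = rlnorm(n, -3.5, 1),
    CODMn = runif(n, 0, 5)
  )
  m
}

# Independent brute-force evaluation of the entropy-weight chain,
# written directly from the defining formulas (kept deliberately naive
# and separate from the package implementation).
brute_force_weights <- function(x, polarity) {
  n <- nrow(x)
  std <- x
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    std[, j] <- if (hi == lo) {
      rep(1, n)
    } else if (polarity[j] == "benefit") {
      (x[, j] - lo) / (hi - lo)
    } else {
      (hi - x[, j]) / (hi - lo)
    }
  }
  E <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    p <- std[, j] / sum(std[, j])
    s <- 0
    for (i in seq_len(n)) if (p[i] > 0) s <- s + p[i] * log(p[i])
    E[j] <- -s / log(n)
  }
  (1 - E) / sum(1 - E)
}
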