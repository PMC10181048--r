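# Independent naive-loop implementation of the whole index chain, kept
# deliberately element-by-element so it shares no code path with the package.
naive_siig <- function(X, signs) {
  n <- nrow(X)
  m <- ncol(X)
  R <- matrix(0, n, m)
  for (j in seq_len(m)) {
    ss <- 0
    for (i in seq_len(n)) ss <- ss + X[i, j]^2
    for (i in seq_len(n)) R[i, j] <- X[i, j] / sqrt(ss)
  }
  rp <- numeric(m)
  rn <- numeric(m)
  for (j in seq_len(m)) {
    hi <- R[1, j]
    lo <- R[1, j]
    for (i in seq_len(n)) {
      if (R[i, j] > hi) hi <- R[i, j]
      if (R[i, j] < lo) lo <- R[i, j]
    }
    if (signs[j] > 0) {
      rp[j] <- hi
      rn[j] <- lo
    } else {
      rp[j] <- lo
      rn[j] <- hi
    }
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    dp <- 0
    dn <- 0
    for (j in seq_len(m)) {
      dp <- dp + (R[i, j] - rp[j])^2
      dn <- dn + (R[i, j] - rn[j])^2
    }
    s[i] <- sqrt(dn) / (sqrt(dp) + sqrt(dn))
  }
  s
}

# Small random trait matrix with positive entries and generic direction spec.
random_trait_matrix <- function(n, m) {
  matrix(stats::runif(n * m, 1, 100), n, m,
         dimnames = list(paste0("g", seq_len(n)), paste0("t", seq_len(m))))
}

random_directions <- function(m) {
  stats::setNames(sample(c("benefit", "cost"), m, replace = TRUE),
                  paste0("t", seq_len(m)))
}
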