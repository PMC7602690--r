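# Shared fixtures: all data is built in code at test time.

# tiny well-formed landmark CSV (S records, n landmarks), returns its path
write_tiny_csv <- function(S = 2L, n = 8L, seed = 1L, path = tempfile(fileext = ".csv")) {
  set.seed(seed)
  coords <- matrix(round(runif(S * 2 * n), 6), S, 2 * n)
  df <- data.frame(subject_id = paste0("s", seq_len(S)), rep_index = 1L,
                   gender = rep(c("F", "M"), length.out = S), coords)
  names(df)[-(1:3)] <- c(paste0("x", 1:n), paste0("y", 1:n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# small labelled dataset from raw pieces
toy_dataset <- function(coords, gender = NULL) {
  S <- nrow(coords)
  if (is.null(gender)) gender <- rep(c("F", "M"), length.out = S)
  landmark_dataset(coords, subject_id = paste0("s", seq_len(S)),
                   rep_index = rep(1L, S), gender = gender)
}

# full-rank reference Gaussian log-pdf, written independently of the
# package's eigen-based evaluation path
ref_mvn_logpdf <- function(x, mean, cov) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  d <- length(mean)
  ci <- solve(cov)
  ld <- determinant(cov, logarithm = TRUE)$modulus
  xc <- sweep(x, 2L, mean)
  drop(-rowSums((xc %*% ci) * xc) / 2 - (d * log(2 * pi) + ld) / 2)
}

# brute-force auROC: P(score_A > score_B) + 0.5 P(equal) over all pairs
brute_auroc <- function(scores, labels) {
  a <- scores[labels]
  b <- scores[!labels]
  g <- outer(a, b, ">")
  e <- outer(a, b, "==")
  mean(g + 0.5 * e)
}

# independent eigen-based pseudo-inverse for planted-parameter checks
sym_pseudo_inverse_oracle <- function(m, rel_tol = 1e-10) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- es$values > rel_tol * max(es$values)
  es$vectors[, keep, drop = FALSE] %*%
    ((1 / es$values[keep]) * t(es$vectors[, keep, drop = FALSE]))
}

# cheap learn parameters for cubic fits in fast tests
fast_learn <- list(n_chains = 64L, max_iters = 400L, burn_in = 150L)
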