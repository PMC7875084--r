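# Independent oracles and fixture builders, deliberately naive: explicit
# inverses and determinants, product-form multivariate gamma.

naive_wishart_log_pdf <- function(m, s, n) {
  p <- nrow(s)
  lg <- p * (p - 1) / 4 * log(pi) + sum(lgamma((n + 1 - seq_len(p)) / 2))
  -(n * p / 2) * log(2) - lg - (n / 2) * log(det(s)) +
    ((n - p - 1) / 2) * log(det(m)) - 0.5 * sum(diag(solve(s) %*% m))
}

rand_spd <- function(p, jitter = 0.1) {
  a <- matrix(stats::rnorm(p * p), p)
  crossprod(a) + diag(jitter, p)
}

# quick labeled element set: k per class, dimension p, identical-law unless
# scales differ
make_two_class_elements <- function(scale_a, scale_b, k = 5, lengths = c(40, 80),
                                    seed = 1) {
  p <- nrow(scale_a)
  spec <- synthetic_spec(p, scale_a = scale_a, scale_b = scale_b,
                         n_elements_a = k, n_elements_b = k,
                         length_range = lengths, seed = seed)
  generate_elements(spec)
}

ratio_cols <- function(scores) grep("^ratio_", names(scores), value = TRUE)
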