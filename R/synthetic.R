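# Two-class synthetic data with the generative structure the Wishart null
# model assumes: mean-zero Gaussian observation vectors, class-specific
# covariance, uneven per-element series lengths.

#' Specify a two-class synthetic dataset
#'
#' Each element of a class is an independent series of `T_i` mean-zero
#' Gaussian p-vectors with the class covariance, `T_i` drawn uniformly from
#' `length_range` (so elements are unevenly sampled, with `L_min >= p`
#' guaranteeing every element satisfies `dof >= p`). Class B's effective
#' covariance is the interpolation `(1 - separation) * scale_a + separation
#' * scale_b`: `separation = 0` makes the classes identically distributed
#' and `separation = 1` uses `scale_b` as given.
#'
#' @param p dimension (number of channels).
#' @param scale_a,scale_b true class covariance matrices (SPD, p x p).
#' @param n_elements_a,n_elements_b elements per class (>= 1).
#' @param length_range integer interval `c(L_min, L_max)` with `L_min >= p`.
#' @param separation interpolation parameter in `[0, 1]` (default 1).
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(p, scale_a, scale_b = scale_a,
                           n_elements_a = 30L, n_elements_b = 30L,
                           length_range = c(5L * p, 10L * p),
                           separation = 1, seed = 1L) {
  p <- check_count(p, "p")
  scale_a <- as_spd(scale_a)
  scale_b <- as_spd(scale_b)
  if (scale_a$p != p || scale_b$p != p) {
    abort_ws("spec_error", "scale matrices must be p x p")
  }
  if (!is.numeric(n_elements_a) || n_elements_a < 1L ||
      !is.numeric(n_elements_b) || n_elements_b < 1L) {
    abort_ws("spec_error", "each class needs at least one element")
  }
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < p) {
    abort_ws("spec_error",
             sprintf("length_range must be [L_min, L_max] with L_min >= p = %d", p))
  }
  if (!is.numeric(separation) || separation < 0) {
    abort_ws("spec_error", "separation must be non-negative")
  }
  structure(
    list(p = p, scale_a = scale_a, scale_b = scale_b,
         n_elements_a = check_count(n_elements_a, "n_elements_a"),
         n_elements_b = check_count(n_elements_b, "n_elements_b"),
         length_range = as.integer(length_range),
         separation = separation, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Spec with informative features planted in class B
#'
#' Builds `scale_a = I` and a `scale_b` that differs from the identity only
#' on the informative rows/columns: variances inflated to `1 + effect` and
#' pairwise correlation among informative features set to
#' `effect / (1 + effect)` (so the off-diagonal covariance equals `effect`).
#' The informative block is `I + effect * J` (eigenvalues `1` and
#' `1 + k * effect`), hence SPD for any `effect > 0`.
#'
#' @param p dimension.
#' @param informative integer indices of planted features (proper subset of
#'   `1:p`).
#' @param effect positive effect size.
#' @param ... further arguments to [synthetic_spec()] (element counts,
#'   `length_range`, `seed`, ...).
#' @return A `synthetic_spec`.
#' @export
planted_feature_spec <- function(p, informative, effect = 1, ...) {
  p <- check_count(p, "p")
  informative <- unique(as.integer(informative))
  if (length(informative) &&
      (min(informative) < 1L || max(informative) > p)) {
    abort_ws("spec_error", sprintf("informative indices must lie in 1..%d", p))
  }
  if (length(informative) >= p) {
    abort_ws("spec_error", "informative features must be a proper subset")
  }
  if (!is.numeric(effect) || effect <= 0) {
    abort_ws("spec_error", "effect must be positive")
  }
  sb <- diag(p)
  if (length(informative)) {
    rho <- effect / (1 + effect)
    sb[informative, informative] <- (1 + effect) * rho
    diag(sb)[informative] <- 1 + effect
  }
  synthetic_spec(p, scale_a = diag(p), scale_b = sb, ...)
}

#' Generate the dataset a spec describes
#'
#' Fully reproducible: the same spec (including seed) yields bit-identical
#' batches. Returns both the data and a truth record for recovery tests.
#'
#' @param spec a `synthetic_spec`.
#' @param labels length-2 character vector of class labels.
#' @return A list with `batches` (list of `batch_series`, class A first) and
#'   `truth` (seed, true/effective covariances, per-element lengths).
#' @export
generate_dataset <- function(spec, labels = c("A", "B")) {
  if (!inherits(spec, "synthetic_spec")) {
    abort_ws("spec_error", "`spec` must come from synthetic_spec()")
  }
  sb_eff <- validate_spd((1 - spec$separation) * spec$scale_a$values +
                           spec$separation * spec$scale_b$values)
  chols <- list(spec$scale_a$chol, sb_eff$chol)
  counts <- c(spec$n_elements_a, spec$n_elements_b)
  with_seed(spec$seed, {
    choices <- seq(spec$length_range[1], spec$length_range[2])
    lengths <- if (length(choices) == 1L) rep(choices, sum(counts))
               else sample(choices, sum(counts), replace = TRUE)
    cls <- rep(1:2, counts)
    batches <- lapply(seq_along(cls), function(i) {
      t_i <- lengths[i]
      x <- matrix(stats::rnorm(t_i * spec$p), nrow = t_i) %*% chols[[cls[i]]]
      colnames(x) <- paste0("f", seq_len(spec$p))
      batch_series(x, label = labels[cls[i]])
    })
    list(batches = batches,
         truth = list(seed = spec$seed,
                      scale_a = spec$scale_a$values,
                      scale_b_effective = sb_eff$values,
                      labels = labels[cls],
                      lengths = lengths))
  })
}

#' Generate a synthetic dataset directly as elements
#'
#' Convenience wrapper: [generate_dataset()] followed by
#' [batches_to_elements()].
#'
#' @inheritParams generate_dataset
#' @param statistic,... passed to [batch_to_element()].
#' @return A list of labeled `element_sample`s.
#' @export
generate_elements <- function(spec, labels = c("A", "B"),
                              statistic = "covariance", ...) {
  ds <- generate_dataset(spec, labels = labels)
  batches_to_elements(ds$batches, statistic = statistic, ...)$elements
}

#' Write a truth record as plain text
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param path file path.
#' @export
write_truth_record <- function(truth, path) {
  fmt_mat <- function(m) paste(apply(m, 1, paste, collapse = " "), collapse = "; ")
  lines <- c(
    sprintf("seed\t%d", truth$seed),
    sprintf("labels\t%s", paste(truth$labels, collapse = ",")),
    sprintf("lengths\t%s", paste(truth$lengths, collapse = ",")),
    sprintf("scale_a\t%s", fmt_mat(truth$scale_a)),
    sprintf("scale_b_effective\t%s", fmt_mat(truth$scale_b_effective))
  )
  writeLines(lines, path)
  invisible(path)
}
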