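# Wishart density (log space) and random sampling by the Gaussian
# outer-product construction.

#' Log multivariate gamma function
#'
#' Computes \eqn{\log \Gamma_p(a) = \frac{p(p-1)}{4}\log\pi +
#' \sum_{i=1}^{p} \log\Gamma\big(\frac{2a + 1 - i}{2}\big)}, the normalizing
#' constant of the Wishart density, entirely in log space.
#'
#' @param p positive integer dimension.
#' @param a real argument; requires `2 * a + 1 - p > 0` so that every
#'   univariate gamma argument is positive.
#' @return `log(Gamma_p(a))` as a single numeric value.
#' @export
log_multivariate_gamma <- function(p, a) {
  p <- check_count(p, "p")
  if (!is.numeric(a) || length(a) != 1L || is.na(a)) {
    abort_ws("domain_error", "`a` must be a single numeric value")
  }
  if (2 * a + 1 - p <= 0) {
    abort_ws("domain_error",
             sprintf("log_multivariate_gamma undefined: need 2a + 1 - p > 0 (a = %g, p = %d)", a, p))
  }
  p * (p - 1) / 4 * log(pi) + sum(lgamma((2 * a + 1 - seq_len(p)) / 2))
}

check_dof <- function(dof, p) {
  if (!is.numeric(dof) || length(dof) != 1L || is.na(dof) || dof != as.integer(dof)) {
    abort_ws("degrees_of_freedom_error", "`dof` must be a single integer")
  }
  if (dof < p) {
    abort_ws("degrees_of_freedom_error",
             sprintf("dof = %d is below the dimension p = %d; the density is undefined", as.integer(dof), p))
  }
  as.integer(dof)
}

validate_scale <- function(scale, ridge = 0) {
  tryCatch({
    if (ridge > 0) {
      validate_spd(if (inherits(scale, "spd_matrix")) scale$values else scale,
                   ridge = ridge)
    } else {
      as_spd(scale)
    }
  }, wishartscore_error = function(e) {
    abort_ws("singular_scale_error",
             paste0("scale matrix is not usable: ", conditionMessage(e)))
  })
}

#' Wishart log density
#'
#' Evaluates \eqn{\log f(M; n, \Sigma) = -\frac{np}{2}\log 2 -
#' \log\Gamma_p(n/2) - \frac{n}{2}\log|\Sigma| +
#' \frac{n-p-1}{2}\log|M| - \frac{1}{2}\mathrm{tr}(\Sigma^{-1}M)} for a
#' p x p matrix `m` under the Wishart law with integer degrees of freedom
#' `dof` (>= p) and symmetric positive-definite scale matrix `scale`.
#'
#' All determinants come from Cholesky factors and the trace is computed by
#' triangular solves (never forming the explicit inverse), so the density is
#' stable at dimensions and degrees of freedom where the closed form
#' under/overflows. The density is zero off the SPD cone: a non-SPD `m`
#' yields `-Inf` rather than an error.
#'
#' @param m matrix to evaluate (`spd_matrix` or square numeric matrix).
#' @param scale SPD scale matrix (Sigma), same dimension as `m`.
#' @param dof integer degrees of freedom, `dof >= p`.
#' @param ridge optional non-negative ridge added to `scale` before
#'   factorization (default 0: the literal model).
#' @return The log density (single numeric; `-Inf` for non-SPD `m`).
#' @export
wishart_log_pdf <- function(m, scale, dof, ridge = 0) {
  scale <- validate_scale(scale, ridge = ridge)
  p <- scale$p
  dof <- check_dof(dof, p)
  mdim <- if (inherits(m, "spd_matrix")) m$p else {
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      abort_ws("dimension_mismatch_error", "`m` must be a square matrix")
    }
    nrow(m)
  }
  if (mdim != p) {
    abort_ws("dimension_mismatch_error",
             sprintf("matrix is %d x %d but scale is %d x %d", mdim, mdim, p, p))
  }
  m <- tryCatch(as_spd(m), wishartscore_error = function(e) NULL)
  if (is.null(m)) return(-Inf)
  # tr(Sigma^-1 M) = ||Ls^-1 Lm||_F^2 with Sigma = Ls Ls', M = Lm Lm'
  lm <- t(m$chol)
  ls <- t(scale$chol)
  w <- forwardsolve(ls, lm)
  tr <- sum(w * w)
  -(dof * p / 2) * log(2) - log_multivariate_gamma(p, dof / 2) -
    (dof / 2) * spd_log_det(scale) + ((dof - p - 1) / 2) * spd_log_det(m) -
    tr / 2
}

#' Sample Wishart-distributed matrices
#'
#' Draws matrices from \eqn{W_p(n, \Sigma)} by the defining construction:
#' each draw is \eqn{\sum_{i=1}^{n} X_i X_i'} with
#' \eqn{X_i \sim N_p(0, \Sigma)}, realized as \eqn{A\,W_p(n, I)\,A'} where
#' `A` is the lower-triangular Cholesky factor of `scale`.
#'
#' @param scale SPD scale matrix Sigma.
#' @param dof integer degrees of freedom n (number of Gaussian vectors
#'   summed; any positive integer is a valid sampling count, but `dof >= p`
#'   is required for the draws to be positive-definite almost surely).
#' @param n_draws number of matrices to draw (0 gives an empty list).
#' @param seed mandatory integer seed; the global RNG state is untouched.
#' @return A list of `n_draws` validated `spd_matrix` objects.
#' @export
sample_wishart <- function(scale, dof, n_draws, seed) {
  scale <- validate_scale(scale)
  p <- scale$p
  dof <- check_dof(dof, p)
  n_draws <- check_count(n_draws, "n_draws", min = 0L)
  if (n_draws == 0L) return(list())
  a_t <- scale$chol  # upper factor; X = Z %*% a_t has rows ~ N(0, Sigma)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      z <- matrix(stats::rnorm(dof * p), nrow = dof, ncol = p)
      x <- z %*% a_t
      validate_spd(crossprod(x))
    })
  })
}
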