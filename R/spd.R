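# Symmetric positive-definite matrix validation and principal submatrices.

#' Validate a symmetric positive-definite matrix
#'
#' Checks that `values` is a square, symmetric (within tolerance),
#' positive-definite real matrix and returns an `spd_matrix` object carrying
#' the symmetrized values and their upper Cholesky factor. Positive
#' definiteness is established by attempting a Cholesky factorization rather
#' than an eigendecomposition: the factorization is needed downstream for
#' log-determinants and trace terms anyway, and a factor with strictly
#' positive diagonal (relative to `pd_tol`) certifies definiteness.
#'
#' @param values square numeric matrix.
#' @param sym_tol relative symmetry tolerance: the matrix is accepted (and
#'   symmetrized to `(A + t(A)) / 2`) when `max(abs(A - t(A)))` does not
#'   exceed `sym_tol * max(abs(A))`.
#' @param pd_tol relative positive-definiteness tolerance: every squared
#'   Cholesky pivot must exceed `pd_tol * max(diag(A))`.
#' @param ridge non-negative scalar; when positive, `ridge * I` is added
#'   before factorization. Off by default so the method stays literal;
#'   useful for near-singular correlation matrices (e.g. collinear channels).
#' @return An object of class `spd_matrix`: a list with `values` (the
#'   symmetrized, optionally ridged matrix), `p`, `chol` (upper triangular),
#'   and `is_correlation` (unit diagonal within tolerance).
#' @examples
#' validate_spd(diag(2))
#' @export
validate_spd <- function(values, sym_tol = 1e-8, pd_tol = 1e-10, ridge = 0) {
  if (inherits(values, "spd_matrix")) return(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_ws("non_square_error", "`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    abort_ws("non_square_error",
             sprintf("matrix is %d x %d, not square", nrow(values), ncol(values)))
  }
  if (anyNA(values)) abort_ws("domain_error", "matrix contains missing values")
  p <- nrow(values)
  scale_mag <- max(abs(values))
  asym <- max(abs(values - t(values)))
  if (asym > sym_tol * max(scale_mag, .Machine$double.xmin)) {
    abort_ws("asymmetric_error",
             sprintf("asymmetry %.3g exceeds tolerance %.3g", asym, sym_tol * scale_mag))
  }
  a <- (values + t(values)) / 2
  if (ridge < 0) abort_ws("domain_error", "`ridge` must be non-negative")
  if (ridge > 0) a <- a + diag(ridge, p)
  max_diag <- max(diag(a))
  if (max_diag <= 0) {
    abort_ws("not_positive_definite_error", "no positive diagonal entry")
  }
  r <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(r) || any(diag(r)^2 <= pd_tol * max_diag)) {
    abort_ws("not_positive_definite_error",
             "Cholesky factorization failed: matrix is not positive-definite within tolerance")
  }
  nms <- colnames(values) %||% paste0("f", seq_len(p))
  dimnames(a) <- list(nms, nms)
  structure(
    list(values = a, p = p, chol = r,
         is_correlation = all(abs(diag(a) - 1) <= max(sym_tol, 1e-8))),
    class = "spd_matrix"
  )
}

#' @export
print.spd_matrix <- function(x, ...) {
  cat(sprintf("<spd_matrix> %d x %d%s\n", x$p, x$p,
              if (x$is_correlation) " (correlation)" else ""))
  print(x$values, ...)
  invisible(x)
}

#' @export
dim.spd_matrix <- function(x) c(x$p, x$p)

#' @export
as.matrix.spd_matrix <- function(x, ...) x$values

spd_log_det <- function(x) 2 * sum(log(diag(x$chol)))

feature_names <- function(x) colnames(as_spd(x)$values)

as_spd <- function(x, ...) {
  if (inherits(x, "spd_matrix")) x else validate_spd(x, ...)
}

#' Principal submatrix by feature deletion
#'
#' Removes the listed rows *and* identically indexed columns. Principal
#' submatrices of a symmetric positive-definite matrix are themselves
#' symmetric positive-definite, so the result is revalidated and returned as
#' an `spd_matrix`.
#'
#' @param m an `spd_matrix` or square numeric matrix.
#' @param delete integer vector of 1-based feature indices to delete; must be
#'   a proper subset of `1:p` (possibly empty).
#' @return An `spd_matrix` of dimension `p - length(delete)`.
#' @export
principal_submatrix <- function(m, delete = integer()) {
  m <- as_spd(m)
  delete <- unique(as.integer(delete))
  if (length(delete) && (min(delete) < 1L || max(delete) > m$p)) {
    abort_ws("index_error",
             sprintf("deletion indices must lie in 1..%d", m$p))
  }
  if (length(delete) == m$p) {
    abort_ws("empty_result_error", "cannot delete every feature")
  }
  if (!length(delete)) return(m)
  keep <- setdiff(seq_len(m$p), delete)
  validate_spd(m$values[keep, keep, drop = FALSE])
}
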