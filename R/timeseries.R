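# Labeled multivariate time series -> constant-label batches -> elements.

#' Create a batch of contiguous, constant-label time points
#'
#' @param data T x p numeric matrix (rows = time points, columns = channels).
#' @param label class label shared by all points of the batch.
#' @param t_start,t_end 0-based half-open indices into the source series.
#' @return An object of class `batch_series`.
#' @export
batch_series <- function(data, label, t_start = 0L, t_end = nrow(data)) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    abort_ws("domain_error", "batch data must be a numeric matrix with >= 1 row")
  }
  t_start <- check_count(t_start, "t_start", min = 0L)
  t_end <- check_count(t_end, "t_end", min = 1L)
  if (t_end - t_start != nrow(data)) {
    abort_ws("length_mismatch_error", "t_end - t_start must equal nrow(data)")
  }
  if (is.null(colnames(data))) colnames(data) <- paste0("f", seq_len(ncol(data)))
  structure(list(data = data, label = as.character(label),
                 t_start = t_start, t_end = t_end),
            class = "batch_series")
}

#' @export
print.batch_series <- function(x, ...) {
  cat(sprintf("<batch_series> label=%s T=%d p=%d [%d, %d)\n",
              x$label, nrow(x$data), ncol(x$data), x$t_start, x$t_end))
  invisible(x)
}

#' Split a labeled series into constant-label batches
#'
#' Maximal runs of constant label, in temporal order, covering the series
#' exactly once: row-concatenating the batch data reproduces the input.
#'
#' @param series T x p numeric matrix.
#' @param labels length-T label vector.
#' @return A list of `batch_series` with 0-based half-open `[t_start,
#'   t_end)` positions.
#' @export
split_batches <- function(series, labels) {
  if (!is.matrix(series)) series <- as.matrix(series)
  if (nrow(series) != length(labels)) {
    abort_ws("length_mismatch_error",
             sprintf("series has %d rows but %d labels", nrow(series), length(labels)))
  }
  if (nrow(series) < 1L) abort_ws("length_mismatch_error", "empty series")
  runs <- rle(as.character(labels))
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  mapply(function(s, e, lab) {
    batch_series(series[(s + 1L):e, , drop = FALSE], lab, t_start = s, t_end = e)
  }, starts, ends, runs$values, SIMPLIFY = FALSE)
}

#' Extract an element (matrix + degrees of freedom) from one batch
#'
#' Computes the p x p sample covariance (divisor T by default, the scatter
#' convention `crossprod(X) / T` after per-batch mean centering) or Pearson
#' correlation matrix of the batch, with `dof` equal to the batch length T.
#' Batches shorter than the number of channels cannot yield a valid Wishart
#' argument and are dropped (returning `NULL`) or raise, per policy.
#'
#' @param batch a `batch_series`.
#' @param statistic `"covariance"` or `"correlation"`.
#' @param min_length_policy `"drop"` (return `NULL` for T < p) or `"error"`.
#' @param center subtract per-channel batch means first (default TRUE; the
#'   model assumes mean-zero observation vectors).
#' @param divisor `"n"` (default, matching the scatter/n convention) or
#'   `"n-1"` for the unbiased covariance.
#' @param ridge passed to [validate_spd()]; lets degenerate (e.g. collinear)
#'   batches through at the user's request.
#' @param element_id optional id for the resulting element.
#' @return An `element_sample`, or `NULL` when dropped.
#' @export
batch_to_element <- function(batch,
                             statistic = c("covariance", "correlation"),
                             min_length_policy = c("drop", "error"),
                             center = TRUE,
                             divisor = c("n", "n-1"),
                             ridge = 0,
                             element_id = NULL) {
  statistic <- match.arg(statistic)
  min_length_policy <- match.arg(min_length_policy)
  divisor <- match.arg(divisor)
  if (!inherits(batch, "batch_series")) {
    abort_ws("domain_error", "`batch` must be a batch_series")
  }
  x <- batch$data
  n <- nrow(x)
  p <- ncol(x)
  if (n < p) {
    if (min_length_policy == "error") {
      abort_ws("batch_too_short_error",
               sprintf("batch length %d < %d channels", n, p))
    }
    return(NULL)
  }
  if (center) x <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(x^2))
  if (statistic == "correlation" && any(sds == 0)) {
    abort_ws("degenerate_channel_error",
             sprintf("zero-variance channel(s): %s",
                     paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  m <- switch(statistic,
              covariance = crossprod(x) / if (divisor == "n") n else (n - 1L),
              correlation = crossprod(sweep(x, 2, sds, "/")))
  if (statistic == "correlation") diag(m) <- 1
  element_sample(m, dof = n, label = batch$label,
                 element_id = element_id, ridge = ridge)
}

#' Convert a batch list to elements, tracking drops
#'
#' @param batches list of `batch_series`.
#' @param ... passed to [batch_to_element()].
#' @return A list with `elements` (the retained `element_sample`s, ids
#'   `batch_0001`, ...) and `n_dropped` / `dropped_ids` for batches shorter
#'   than the channel count under the `drop` policy.
#' @export
batches_to_elements <- function(batches, ...) {
  ids <- sprintf("batch_%04d", seq_along(batches))
  out <- mapply(function(b, id) batch_to_element(b, element_id = id, ...),
                batches, ids, SIMPLIFY = FALSE)
  keep <- !vapply(out, is.null, logical(1))
  list(elements = out[keep], n_dropped = sum(!keep), dropped_ids = ids[!keep])
}

#' Read a labeled multivariate series from delimited text or ARFF
#'
#' Expects one row per time point, p channel columns and one label column.
#' ARFF (the native format of several public EEG datasets) is read via
#' `foreign::read.arff`; anything else is treated as delimited text with a
#' header.
#'
#' @param path file path.
#' @param label_col name of the label column (default: last column).
#' @param sep field separator for delimited text (default: auto `,` or tab
#'   from the extension).
#' @return A list with `series` (T x p matrix) and `labels` (length-T
#'   character vector).
#' @export
read_labeled_series <- function(path, label_col = NULL, sep = NULL) {
  if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    df <- foreign::read.arff(path)
  } else {
    sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  }
  label_col <- label_col %||% names(df)[ncol(df)]
  if (!label_col %in% names(df)) {
    abort_ws("domain_error", sprintf("no label column `%s`", label_col))
  }
  labels <- as.character(df[[label_col]])
  series <- as.matrix(df[setdiff(names(df), label_col)])
  if (!is.numeric(series)) {
    abort_ws("domain_error", "channel columns must all be numeric")
  }
  list(series = series, labels = labels)
}
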