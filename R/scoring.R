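# Log-likelihood-ratio scores: complete-matrix, single-feature deletion,
# group deletion, and the dataset-wide feature transformation.

eval_matrix <- function(element, mode) {
  switch(mode,
         literal = element$matrix,
         scatter = validate_spd(element$dof * element$matrix$values))
}

check_score_inputs <- function(element, model, mode) {
  if (!inherits(element, "element_sample")) {
    abort_ws("domain_error", "`element` must be an element_sample")
  }
  if (!inherits(model, "class_model")) {
    abort_ws("domain_error", "`model` must be a class_model")
  }
  if (element$matrix$p != model$scale$p) {
    abort_ws("dimension_mismatch_error",
             sprintf("element is %d-dimensional, model %d-dimensional",
                     element$matrix$p, model$scale$p))
  }
  invisible(NULL)
}

#' Complete-matrix log-likelihood-ratio score
#'
#' \eqn{\mathrm{score}_i = \log P_W(\Sigma_i \mid n_i, \hat\Sigma_A) -
#' \log P_W(\Sigma_i \mid n_i, \hat\Sigma_B)}: the log density of the
#' element's matrix under class A's Wishart model minus the same under class
#' B's, both at the element's own degrees of freedom. Positive values favor
#' class A; swapping the models negates the score.
#'
#' @param element `element_sample` to score.
#' @param model_a,model_b fitted `class_model`s of the two classes.
#' @param mode `"literal"` (default) evaluates the density of the element's
#'   matrix itself; `"scatter"` evaluates the density of `dof * matrix`
#'   (the scatter matrix with Wishart expectation `dof * scale`). The choice
#'   shifts absolute log-likelihoods but both classes shift together.
#' @return Single numeric score.
#' @export
complete_score <- function(element, model_a, model_b,
                           mode = c("literal", "scatter")) {
  mode <- match.arg(mode)
  check_score_inputs(element, model_a, mode)
  check_score_inputs(element, model_b, mode)
  m <- eval_matrix(element, mode)
  wishart_log_pdf(m, model_a$scale, element$dof) -
    wishart_log_pdf(m, model_b$scale, element$dof)
}

#' Single-feature deletion scores against one class
#'
#' For each feature j, the change in class log-likelihood caused by deleting
#' j: \eqn{\Delta\log P_W^{(j)}(C) = \log P_W(\Sigma \mid n, \hat\Sigma_C) -
#' \log P_W(\Sigma_{(j)} \mid n, \hat\Sigma_{C,(j)})}, where both the
#' element's matrix and the class scale matrix have row and column j removed
#' in the second term. The full-matrix term is computed once and shared
#' across all p entries, so the cost is p + 1 density evaluations.
#'
#' @inheritParams complete_score
#' @param model a fitted `class_model`.
#' @return Named numeric vector of length p (names = feature names).
#' @export
single_feature_scores <- function(element, model,
                                  mode = c("literal", "scatter")) {
  mode <- match.arg(mode)
  check_score_inputs(element, model, mode)
  m <- eval_matrix(element, mode)
  p <- m$p
  full <- wishart_log_pdf(m, model$scale, element$dof)
  sub <- vapply(seq_len(p), function(j) {
    wishart_log_pdf(principal_submatrix(m, j),
                    principal_submatrix(model$scale, j),
                    element$dof)
  }, numeric(1))
  stats::setNames(full - sub, feature_names(m))
}

#' Group-deletion score against one class
#'
#' Generalizes the single-feature score to deleting a set of k features at
#' once: the log-likelihood change between the full matrix and the
#' (p-k)-dimensional principal submatrices of both the element and the class
#' scale matrix. With a singleton set this equals the corresponding entry of
#' [single_feature_scores()]; with an empty set it is 0.
#'
#' @inheritParams single_feature_scores
#' @param delete integer vector of feature indices to delete (proper subset
#'   of `1:p`).
#' @return Single numeric score.
#' @export
group_feature_score <- function(element, model, delete,
                                mode = c("literal", "scatter")) {
  mode <- match.arg(mode)
  check_score_inputs(element, model, mode)
  m <- eval_matrix(element, mode)
  if (!length(delete)) return(0)
  wishart_log_pdf(m, model$scale, element$dof) -
    wishart_log_pdf(principal_submatrix(m, delete),
                    principal_submatrix(model$scale, delete),
                    element$dof)
}

#' Two-class score vector for one element
#'
#' The element's transformed feature representation: per feature j,
#' \eqn{\mathrm{Ratio}_j = \Delta\log P_W^{(j)}(C_A) -
#' \Delta\log P_W^{(j)}(C_B)}, plus the complete-matrix score. Swapping the
#' two models negates every entry.
#'
#' @inheritParams complete_score
#' @return An object of class `score_vector`: list with `element_id`,
#'   `label`, `complete_score`, `per_feature` (named length-p vector) and
#'   `is_correlation`.
#' @export
score_ratio_vector <- function(element, model_a, model_b,
                               mode = c("literal", "scatter")) {
  mode <- match.arg(mode)
  da <- single_feature_scores(element, model_a, mode = mode)
  db <- single_feature_scores(element, model_b, mode = mode)
  structure(
    list(element_id = element$element_id,
         label = element$label,
         complete_score = complete_score(element, model_a, model_b, mode = mode),
         per_feature = da - db,
         classes = c(model_a$label, model_b$label),
         is_correlation = element$matrix$is_correlation),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> id=%s label=%s (%s vs %s) complete=%.4g\n",
              x$element_id, x$label, x$classes[1], x$classes[2],
              x$complete_score))
  print(x$per_feature, ...)
  invisible(x)
}

#' Transform a labeled element set into score vectors
#'
#' The dataset-wide feature transformation: class scale matrices are fitted
#' under the requested exclusion protocol, and every element is scored
#' (complete score + per-feature ratios) with models it did not contribute
#' to. The first class in alphabetical order plays the role of class A, so
#' positive complete scores favor it.
#'
#' @param elements labeled `element_sample` list; exactly two classes, each
#'   with >= 2 members.
#' @param scheme `"leave_one_out"` (default) or `"k_fold"`.
#' @param k,seed passed to [exclusion_folds()] for `k_fold`.
#' @param weighting scale-matrix weighting, see [estimate_scale_matrix()].
#' @param mode density convention, see [complete_score()].
#' @return A data frame with one row per element: `element_id`, `label`,
#'   `complete_score`, then `ratio_<feature>` columns. Attribute `classes`
#'   records the (A, B) class order.
#' @export
transform_dataset <- function(elements,
                              scheme = c("leave_one_out", "k_fold"),
                              k = 10L, seed = NULL,
                              weighting = c("dof_weighted", "uniform"),
                              mode = c("literal", "scatter")) {
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  check_elements(elements, require_labels = TRUE)
  classes <- sort(unique(element_labels(elements)))
  if (length(classes) > 2L) {
    abort_ws("more_than_two_classes_error",
             sprintf("two-class transform got %d classes: %s",
                     length(classes), paste(classes, collapse = ", ")))
  }
  if (length(classes) < 2L) {
    abort_ws("class_too_small_error", "need two distinct class labels")
  }
  models <- fit_with_exclusion(elements, scheme, k = k, seed = seed,
                               weighting = weighting)
  rows <- lapply(elements, function(e) {
    ms <- models[[e$element_id]]
    sv <- score_ratio_vector(e, ms[[classes[1]]], ms[[classes[2]]], mode = mode)
    c(list(element_id = sv$element_id, label = sv$label,
           complete_score = sv$complete_score),
      as.list(stats::setNames(sv$per_feature,
                              paste0("ratio_", names(sv$per_feature)))))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  attr(out, "classes") <- classes
  attr(out, "mode") <- mode
  out
}

#' Write / read a score table as delimited text
#'
#' @param scores data frame from [transform_dataset()].
#' @param path file path (tab-separated text).
#' @return `write_score_table()` the path invisibly; `read_score_table()`
#'   the data frame.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = c(element_id = "character", label = "character"))
}
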