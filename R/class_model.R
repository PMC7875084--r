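# Class-wise Wishart scale matrices: averages of member matrices, with
# exclusion protocols so no element contributes to the model that scores it.

#' Estimate a class scale matrix
#'
#' The scale matrix of a class is the convex combination of its members'
#' matrices: the plain average \eqn{\hat\Sigma_C = \frac{1}{N_C}\sum_i
#' \Sigma_i} (`uniform`), or the average weighted by each member's degrees of
#' freedom \eqn{\hat\Sigma_C = \sum_i \frac{n_i}{\sum_j n_j}\Sigma_i}
#' (`dof_weighted`, the default), which weights time-series batches by their
#' length and reduces to the plain average when all lengths are equal.
#' A convex combination of SPD matrices is SPD, so the result revalidates.
#'
#' The class model stores no degrees of freedom: at scoring time each
#' element is evaluated at its own `dof`.
#'
#' @param members non-empty list of `element_sample`, all of one class and
#'   one dimension.
#' @param weighting `"dof_weighted"` (default) or `"uniform"`.
#' @param label class label; defaults to the members' common label.
#' @return An object of class `class_model` with fields `scale`
#'   (`spd_matrix`), `n_members`, `weighting`, `label`.
#' @export
estimate_scale_matrix <- function(members,
                                  weighting = c("dof_weighted", "uniform"),
                                  label = NULL) {
  weighting <- match.arg(weighting)
  check_elements(members)
  w <- switch(weighting,
              uniform = rep(1, length(members)),
              dof_weighted = vapply(members, function(e) as.numeric(e$dof), numeric(1)))
  w <- w / sum(w)
  p <- members[[1]]$matrix$p
  s <- matrix(0, p, p)
  for (i in seq_along(members)) s <- s + w[i] * members[[i]]$matrix$values
  dimnames(s) <- dimnames(members[[1]]$matrix$values)
  structure(
    list(scale = validate_spd(s),
         n_members = length(members),
         weighting = weighting,
         weights = stats::setNames(w, element_ids(members)),
         label = as.character(label %||% members[[1]]$label)),
    class = "class_model"
  )
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> label=%s members=%d weighting=%s p=%d\n",
              x$label, x$n_members, x$weighting, x$scale$p))
  invisible(x)
}

#' Exclusion folds over labeled elements
#'
#' Partitions element ids into held-out sets such that class models fitted on
#' each set's complement never contain a held-out element: singletons for
#' `leave_one_out`; a seeded shuffle dealt round-robin within each class
#' (stratified) for `k_fold`.
#'
#' @param elements labeled `element_sample` list; every class needs >= 2
#'   members so exclusion leaves a non-empty class.
#' @param scheme `"leave_one_out"` or `"k_fold"`.
#' @param k number of folds (`k_fold` only), `2 <= k <= length(elements)`.
#' @param seed integer seed for the shuffle (`k_fold` only).
#' @return A list of character vectors of element ids (the held-out sets).
#' @export
exclusion_folds <- function(elements,
                            scheme = c("leave_one_out", "k_fold"),
                            k = 10L, seed = NULL) {
  scheme <- match.arg(scheme)
  check_elements(elements, require_labels = TRUE)
  labels <- element_labels(elements)
  ids <- element_ids(elements)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    abort_ws("class_too_small_error",
             sprintf("every class needs >= 2 members (got %s)",
                     paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  }
  if (scheme == "leave_one_out") return(as.list(ids))
  k <- check_count(k, "k", min = 2L)
  if (k > length(elements)) {
    abort_ws("class_too_small_error",
             sprintf("k = %d folds but only %d elements", k, length(elements)))
  }
  if (is.null(seed)) abort_ws("seed_error", "k_fold exclusion requires a `seed`")
  # shuffle within class, then deal the class-ordered sequence round-robin so
  # folds are balanced and each class spreads as evenly as possible
  dealt <- with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(cl) {
      members <- which(labels == cl)
      if (length(members) > 1L) sample(members) else members
    }))
  })
  assign_fold <- integer(length(elements))
  assign_fold[dealt] <- (seq_along(dealt) - 1L) %% k + 1L
  folds <- split(ids, assign_fold)
  # a fold must not swallow a whole class
  for (f in folds) {
    left <- table(labels[!ids %in% f])
    if (length(left) < length(sizes)) {
      abort_ws("class_too_small_error",
               "a fold would hold out an entire class; reduce k")
    }
  }
  unname(folds)
}

#' Fit class models under an exclusion protocol
#'
#' For every element, estimates one scale matrix per class from all labeled
#' elements *outside* the element's held-out set, guaranteeing the element's
#' own matrix has zero weight in the model that will score it.
#'
#' @inheritParams exclusion_folds
#' @param weighting passed to [estimate_scale_matrix()].
#' @return A named list, `element_id -> named list of class_model` (one
#'   entry per class label, alphabetical).
#' @export
fit_with_exclusion <- function(elements,
                               scheme = c("leave_one_out", "k_fold"),
                               k = 10L, seed = NULL,
                               weighting = c("dof_weighted", "uniform")) {
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  folds <- exclusion_folds(elements, scheme, k = k, seed = seed)
  ids <- element_ids(elements)
  labels <- element_labels(elements)
  classes <- sort(unique(labels))
  out <- vector("list", length(elements))
  names(out) <- ids
  for (f in folds) {
    train <- elements[!ids %in% f]
    train_labels <- element_labels(train)
    models <- lapply(classes, function(cl) {
      estimate_scale_matrix(train[train_labels == cl], weighting = weighting,
                            label = cl)
    })
    names(models) <- classes
    for (id in f) out[[id]] <- models
  }
  out
}
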