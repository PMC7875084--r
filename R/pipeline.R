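# End-to-end orchestration: series -> batches -> exclusion-fitted class
# models -> score table -> feature ranking -> performance curves.

#' Build a downstream classifier hook
#'
#' The transformation is classifier-agnostic; a single pluggable hook is
#' provided for evaluation. `"svm_linear"` is a C-support vector machine
#' with linear kernel (via e1071, with Platt-scaled probabilities for ROC
#' analysis); `"logistic"` is a plain logistic regression.
#'
#' @param name `"svm_linear"` (default) or `"logistic"`.
#' @param ... extra arguments passed to the underlying fitter.
#' @return A list with `name`, `fit(x, y)`, `predict_label(model, x)` and
#'   `score(model, x)`; the score is a real value increasing with the
#'   evidence for the *second* factor level (used for ROC analysis).
#' @export
make_classifier <- function(name = c("svm_linear", "logistic"), ...) {
  name <- match.arg(name)
  extra <- list(...)
  switch(
    name,
    svm_linear = list(
      name = name,
      fit = function(x, y) {
        x <- as.matrix(x)
        m <- do.call(e1071::svm,
                     c(list(x = x, y = y, kernel = "linear",
                            scale = apply(x, 2, stats::sd) > 0),
                       extra))
        m$.levels <- levels(y)
        m
      },
      predict_label = function(model, x) {
        as.character(stats::predict(model, as.matrix(x)))
      },
      score = function(model, x) {
        pr <- stats::predict(model, as.matrix(x), decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        # decision values are oriented so positive favors the class named
        # first in the column header "L1/L2"
        first <- sub("/.*$", "", colnames(dv)[1])
        if (identical(first, model$.levels[2])) dv[, 1] else -dv[, 1]
      }
    ),
    logistic = list(
      name = name,
      fit = function(x, y) {
        df <- as.data.frame(x)
        df$.y <- y
        m <- suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial())
        )
        m$.levels <- levels(y)
        m
      },
      predict_label = function(model, x) {
        pr <- stats::predict(model, newdata = as.data.frame(x), type = "response")
        model$.levels[(pr > 0.5) + 1L]
      },
      score = function(model, x) {
        stats::predict(model, newdata = as.data.frame(x), type = "response")
      }
    )
  )
}

stratified_cv_folds <- function(y, k, seed) {
  y <- as.character(y)
  dealt <- with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(cl) {
      members <- which(y == cl)
      if (length(members) > 1L) sample(members) else members
    }))
  })
  fold <- integer(length(y))
  fold[dealt] <- (seq_along(dealt) - 1L) %% k + 1L
  fold
}

#' Stratified cross-validated accuracy and AUC
#'
#' @param x numeric feature matrix / data frame (rows = elements).
#' @param y class labels (2 levels).
#' @param k number of folds.
#' @param classifier hook from [make_classifier()].
#' @param seed integer seed for fold assignment.
#' @return List with `accuracy`, `auc` (pooled over held-out folds) and the
#'   per-element `predictions` data frame.
#' @export
cross_validate <- function(x, y, k = 10L, classifier = make_classifier(),
                           seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) {
    abort_ws("more_than_two_classes_error", "cross_validate needs exactly 2 classes")
  }
  k <- check_count(k, "k", min = 2L)
  if (k > length(y)) {
    abort_ws("class_too_small_error", "more folds than elements")
  }
  fold <- stratified_cv_folds(y, k, seed)
  score <- numeric(length(y))
  pred <- character(length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    m <- classifier$fit(x[!test, , drop = FALSE], y[!test])
    score[test] <- classifier$score(m, x[test, , drop = FALSE])
    pred[test] <- classifier$predict_label(m, x[test, , drop = FALSE])
  }
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                        levels = levels(y), direction = "<",
                                        quiet = TRUE)))
  list(accuracy = mean(pred == as.character(y)), auc = auc,
       predictions = data.frame(label = as.character(y), fold = fold,
                                score = score, predicted = pred,
                                stringsAsFactors = FALSE))
}

#' Run the full transformation pipeline
#'
#' Orchestrates batch segmentation, matrix extraction, exclusion-protocol
#' class-model fitting and scoring, surfacing component errors with the
#' failing stage named. Provide either a labeled `series`, a list of
#' `batches`, or `elements` directly.
#'
#' @param series T x p matrix plus `labels`, as for [split_batches()].
#' @param labels length-T label vector (with `series`).
#' @param batches list of `batch_series` (alternative input).
#' @param elements list of `element_sample` (alternative input).
#' @param statistic,min_length_policy,center,divisor,ridge passed to
#'   [batch_to_element()].
#' @param scheme,k,seed,weighting,mode passed to [transform_dataset()].
#' @return List with `scores` (the transformed table) and `manifest`
#'   (settings, class sizes, dropped-batch bookkeeping).
#' @export
run_transform <- function(series = NULL, labels = NULL, batches = NULL,
                          elements = NULL,
                          statistic = c("covariance", "correlation"),
                          min_length_policy = "drop", center = TRUE,
                          divisor = "n", ridge = 0,
                          scheme = c("leave_one_out", "k_fold"),
                          k = 10L, seed = NULL,
                          weighting = c("dof_weighted", "uniform"),
                          mode = c("literal", "scatter")) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  at_stage <- function(stage, expr) {
    withCallingHandlers(expr, wishartscore_error = function(e) {
      e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
      stop(e)
    })
  }
  n_dropped <- 0L
  dropped_ids <- character()
  if (is.null(elements)) {
    if (is.null(batches)) {
      if (is.null(series) || is.null(labels)) {
        abort_ws("domain_error", "provide `series`+`labels`, `batches`, or `elements`")
      }
      batches <- at_stage("split_batches", split_batches(series, labels))
    }
    conv <- at_stage("batch_to_element",
                     batches_to_elements(batches, statistic = statistic,
                                         min_length_policy = min_length_policy,
                                         center = center, divisor = divisor,
                                         ridge = ridge))
    elements <- conv$elements
    n_dropped <- conv$n_dropped
    dropped_ids <- conv$dropped_ids
  }
  scores <- at_stage("transform_dataset",
                     transform_dataset(elements, scheme = scheme, k = k,
                                       seed = seed, weighting = weighting,
                                       mode = mode))
  list(
    scores = scores,
    manifest = list(
      statistic = statistic, weighting = weighting, scheme = scheme,
      k = if (scheme == "k_fold") k else NA_integer_,
      seed = seed %||% NA_integer_, mode = mode,
      center = center, divisor = divisor, ridge = ridge,
      n_elements = length(elements),
      class_sizes = as.list(table(element_labels(elements))),
      n_dropped_batches = n_dropped, dropped_ids = dropped_ids,
      classes = attr(scores, "classes")
    )
  )
}

ratio_columns <- function(scores) {
  cols <- grep("^ratio_", names(scores), value = TRUE)
  if (!length(cols)) {
    abort_ws("empty_table_error", "score table has no ratio_ columns")
  }
  cols
}

#' Rank features by mean absolute ratio score
#'
#' Features are ordered by the mean over elements of `|Ratio_j|`,
#' descending; ties break by ascending feature index. Features whose
#' deletion moves the class log-likelihood ratio most, in either direction,
#' carry the most class-discriminating information.
#'
#' @param scores score table from [transform_dataset()].
#' @return Data frame `feature`, `mean_abs_ratio`, `rank` (best first).
#' @export
rank_features <- function(scores) {
  if (!is.data.frame(scores) || !nrow(scores)) {
    abort_ws("empty_table_error", "empty score table")
  }
  cols <- ratio_columns(scores)
  stat <- vapply(scores[cols], function(v) mean(abs(v)), numeric(1))
  ord <- order(-stat, seq_along(stat))
  data.frame(feature = sub("^ratio_", "", cols)[ord],
             mean_abs_ratio = unname(stat[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Classification performance at increasing numbers of ranked features
#'
#' For k = 1..p, cross-validated performance of the classifier on the top-k
#' ranked ratio features; at k = p this equals full-feature performance.
#'
#' @param scores score table from [transform_dataset()].
#' @param ranking optional output of [rank_features()] (computed if absent).
#' @param classifier hook from [make_classifier()].
#' @param cv_folds number of stratified CV folds (default 10).
#' @param seed integer seed.
#' @return Data frame `n_features`, `feature_added`, `accuracy`, `auc`.
#' @export
incremental_feature_curve <- function(scores, ranking = NULL,
                                      classifier = make_classifier(),
                                      cv_folds = 10L, seed = 1L) {
  ranking <- ranking %||% rank_features(scores)
  cols <- paste0("ratio_", ranking$feature)
  res <- lapply(seq_along(cols), function(kk) {
    cv <- cross_validate(scores[cols[seq_len(kk)]], scores$label,
                         k = cv_folds, classifier = classifier, seed = seed)
    data.frame(n_features = kk, feature_added = ranking$feature[kk],
               accuracy = cv$accuracy, auc = cv$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Performance stability across subsample sizes
#'
#' Repeatedly draws equal-per-class subsamples of each requested size,
#' reruns the transformation (leave-one-out exclusion) on the subsample, and
#' evaluates the classifier by 5-fold stratified cross-validation; reports
#' mean and standard error across repeats. Performance is expected to
#' degrade and destabilize as the subsample size approaches the number of
#' features.
#'
#' @param elements labeled `element_sample` list (two classes).
#' @param sizes per-class subsample sizes.
#' @param repeats number of repeated subsamples per size (>= 2).
#' @param classifier hook from [make_classifier()].
#' @param seed integer seed driving subsampling and CV folds.
#' @param cv_folds folds for the inner cross-validation (default 5).
#' @param weighting,mode passed to [transform_dataset()].
#' @return Data frame `size`, `mean_accuracy`, `se_accuracy`, `mean_auc`,
#'   `se_auc`.
#' @export
subsample_stability <- function(elements, sizes, repeats = 5L,
                                classifier = make_classifier(), seed = 1L,
                                cv_folds = 5L,
                                weighting = "dof_weighted",
                                mode = "literal") {
  check_elements(elements, require_labels = TRUE)
  repeats <- check_count(repeats, "repeats", min = 2L)
  labels <- element_labels(elements)
  classes <- sort(unique(labels))
  min_class <- min(table(labels))
  res <- lapply(sizes, function(s) {
    if (!is.numeric(s) || s < 1 || s != round(s)) {
      abort_ws("size_too_large_error", "sizes must be positive integers")
    }
    if (s > min_class) {
      abort_ws("size_too_large_error",
               sprintf("size %d exceeds smallest class (%d members)", s, min_class))
    }
    accs <- numeric(repeats)
    aucs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sub_seed <- seed + 1000L * r + s
      idx <- sort(with_seed(sub_seed, {
        unlist(lapply(classes, function(cl) sample(which(labels == cl), s)))
      }))
      sc <- transform_dataset(elements[idx], scheme = "leave_one_out",
                              weighting = weighting, mode = mode)
      # CV folds share one seed across repeats, so at full size (identical
      # membership) the only variance source would be subsampling: SE is 0.
      cv <- cross_validate(sc[ratio_columns(sc)], sc$label,
                           k = min(cv_folds, 2L * s), classifier = classifier,
                           seed = seed)
      accs[r] <- cv$accuracy
      aucs[r] <- cv$auc
    }
    data.frame(size = s,
               mean_accuracy = mean(accs),
               se_accuracy = stats::sd(accs) / sqrt(repeats),
               mean_auc = mean(aucs),
               se_auc = stats::sd(aucs) / sqrt(repeats))
  })
  do.call(rbind, res)
}
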