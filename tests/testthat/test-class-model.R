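el <- function(m, dof, label = "A", id) {
  element_sample(m, dof = dof, label = label, element_id = id)
}

test_that("scale estimation averages member matrices correctly", {
  a <- matrix(c(2, 0.5, 0.5, 1), 2)
  twins <- list(el(a, 10, id = "x"), el(a, 30, id = "y"))
  for (w in c("uniform", "dof_weighted")) {
    expect_equal(unname(as.matrix(estimate_scale_matrix(twins, w)$scale)), a)
  }

  # dof-weighted mean: (1/4) * 2I + (3/4) * 4I = 3.5 I
  mix <- list(el(2 * diag(1), 1, id = "u"), el(4 * diag(1), 3, id = "v"))
  expect_equal(as.matrix(estimate_scale_matrix(mix, "dof_weighted")$scale)[1, 1], 3.5)

  pair <- list(el(diag(2), 5, id = "p"), el(3 * diag(2), 9, id = "q"))
  expect_equal(unname(as.matrix(estimate_scale_matrix(pair, "uniform")$scale)),
               2 * diag(2))
  expect_equal(sum(estimate_scale_matrix(pair, "dof_weighted")$weights), 1)
})

test_that("scale estimation rejects empty or mismatched member sets", {
  expect_error(estimate_scale_matrix(list()), class = "empty_class_error")
  expect_error(
    estimate_scale_matrix(list(el(diag(2), 5, id = "a"), el(diag(3), 5, id = "b"))),
    class = "dimension_mismatch_error"
  )
})

test_that("leave-one-out with two members uses exactly the other matrix", {
  a1 <- matrix(c(1, 0.2, 0.2, 1), 2)
  a2 <- matrix(c(2, -0.1, -0.1, 1.5), 2)
  els <- list(el(a1, 10, "A", "a1"), el(a2, 12, "A", "a2"),
              el(diag(2), 10, "B", "b1"), el(0.5 * diag(2), 10, "B", "b2"))
  fits <- fit_with_exclusion(els, "leave_one_out")
  expect_equal(unname(as.matrix(fits[["a1"]][["A"]]$scale)), a2)
  expect_equal(unname(as.matrix(fits[["a2"]][["A"]]$scale)), a1)
  # the other class keeps all members not held out
  expect_equal(fits[["a1"]][["B"]]$n_members, 2L)
})

test_that("no element ever contributes weight to the model that scores it", {
  set.seed(21)
  els <- lapply(1:6, function(i) {
    el(rand_spd(3), 10 + i, label = if (i <= 3) "A" else "B",
       id = paste0("e", i))
  })
  for (setup in list(list("leave_one_out", NULL, NULL),
                     list("k_fold", 3L, 99L))) {
    fits <- fit_with_exclusion(els, setup[[1]], k = setup[[2]] %||% 10L,
                               seed = setup[[3]])
    for (e in els) {
      own <- fits[[e$element_id]][[e$label]]
      expect_false(e$element_id %in% names(own$weights))
      # recompute the weighted sum from the recorded weights: it must
      # reproduce the scale without any contribution from the element
      members <- els[match(names(own$weights), vapply(els, `[[`, "", "element_id"))]
      rebuilt <- Reduce(`+`, Map(function(m, w) w * as.matrix(m$matrix),
                                 members, own$weights))
      expect_equal(unname(as.matrix(own$scale)), unname(rebuilt))
    }
  }
})

test_that("k-fold partitions are stratified, exhaustive and disjoint", {
  set.seed(4)
  els <- lapply(1:10, function(i) {
    el(rand_spd(2), 8, label = if (i %% 2) "A" else "B", id = paste0("e", i))
  })
  folds <- exclusion_folds(els, "k_fold", k = 5, seed = 31)
  all_ids <- sort(unlist(folds))
  expect_identical(all_ids, sort(vapply(els, `[[`, "", "element_id")))
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  # k = N degenerates to leave-one-out partition structure
  loo_like <- exclusion_folds(els, "k_fold", k = 10, seed = 31)
  expect_true(all(lengths(loo_like) == 1L))
})

test_that("exclusion preconditions are enforced", {
  set.seed(5)
  els9 <- lapply(1:9, function(i) {
    el(rand_spd(2), 8, label = if (i <= 5) "A" else "B", id = paste0("e", i))
  })
  expect_error(exclusion_folds(els9, "k_fold", k = 10, seed = 1),
               class = "class_too_small_error")
  lone <- list(el(diag(2), 5, "A", "a"), el(diag(2), 5, "B", "b1"),
               el(2 * diag(2), 5, "B", "b2"))
  expect_error(exclusion_folds(lone, "leave_one_out"),
               class = "class_too_small_error")
  unlab <- list(el(diag(2), 5, NA, "a"), el(diag(2), 5, NA, "b"))
  expect_error(exclusion_folds(unlab, "leave_one_out"),
               class = "unlabeled_element_error")
})

test_that("the class scale matrix converges to the true covariance", {
  truth <- matrix(c(1, 0.4, 0.1, 0.4, 1.5, -0.2, 0.1, -0.2, 0.8), 3)
  errs <- vapply(c(10, 100, 1000), function(nmem) {
    els <- with_seed(17 + nmem, {
      lapply(seq_len(nmem), function(i) {
        x <- matrix(stats::rnorm(50 * 3), 50) %*% chol(truth)
        element_sample(crossprod(x) / 50, dof = 50, label = "A",
                       element_id = paste0("m", i))
      })
    })
    est <- as.matrix(estimate_scale_matrix(els)$scale)
    norm(est - truth, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
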