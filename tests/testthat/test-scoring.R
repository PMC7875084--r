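mk_model <- function(m, dof = 10, label = "A", id = "m1") {
  estimate_scale_matrix(list(element_sample(m, dof, label, id)), label = label)
}

test_that("complete score is zero for identical models and antisymmetric", {
  set.seed(2)
  m <- rand_spd(3)
  e <- element_sample(rand_spd(3), 12, "A", "e1")
  mod_a <- mk_model(m)
  mod_b <- mk_model(rand_spd(3), label = "B", id = "m2")
  expect_equal(complete_score(e, mod_a, mod_a), 0)
  s_ab <- complete_score(e, mod_a, mod_b)
  s_ba <- complete_score(e, mod_b, mod_a)
  expect_equal(s_ab, -s_ba, tolerance = 1e-9)
})

test_that("single-feature scores match the from-scratch submatrix oracle", {
  set.seed(8)
  for (mode in c("literal", "scatter")) {
    p <- 4
    m <- rand_spd(p)
    s <- rand_spd(p)
    n <- 11
    e <- element_sample(m, n, "A", "e1")
    mod <- mk_model(s)
    got <- single_feature_scores(e, mod, mode = mode)
    m_eval <- if (mode == "scatter") n * m else m
    want <- vapply(seq_len(p), function(j) {
      keep <- setdiff(seq_len(p), j)
      naive_wishart_log_pdf(m_eval, s, n) -
        naive_wishart_log_pdf(m_eval[keep, keep], s[keep, keep], n)
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("exchangeable features receive identical scores", {
  e <- element_sample(diag(2), 6, "A", "e1")
  mod <- mk_model(diag(2))
  sc <- single_feature_scores(e, mod)
  expect_equal(sc[[1]], sc[[2]])
})

test_that("group deletion generalizes single-feature deletion", {
  set.seed(13)
  p <- 4
  e <- element_sample(rand_spd(p), 9, "A", "e1")
  mod <- mk_model(rand_spd(p))
  expect_equal(group_feature_score(e, mod, integer()), 0)
  single <- single_feature_scores(e, mod)
  for (j in seq_len(p)) {
    expect_equal(group_feature_score(e, mod, j), unname(single[j]),
                 tolerance = 1e-9)
  }
  # two deletions on a 4-feature problem against the 2x2 remnant densities
  m <- as.matrix(e$matrix)
  s <- as.matrix(mod$scale)
  keep <- c(2, 4)
  want <- naive_wishart_log_pdf(m, s, 9) -
    naive_wishart_log_pdf(m[keep, keep], s[keep, keep], 9)
  expect_equal(group_feature_score(e, mod, c(1, 3)), want, tolerance = 1e-9)
})

test_that("score vectors cancel for identical models and negate under swap", {
  set.seed(19)
  e <- element_sample(rand_spd(5), 20, "A", "e1")
  mod_a <- mk_model(rand_spd(5))
  mod_b <- mk_model(rand_spd(5), label = "B", id = "m2")
  same <- score_ratio_vector(e, mod_a, mod_a)
  expect_equal(unname(same$per_feature), rep(0, 5))
  sv <- score_ratio_vector(e, mod_a, mod_b)
  vs <- score_ratio_vector(e, mod_b, mod_a)
  expect_equal(sv$per_feature, -vs$per_feature, tolerance = 1e-9)
  expect_equal(sv$complete_score, -vs$complete_score, tolerance = 1e-9)
})

test_that("complete score favors the generating class in the literal convention", {
  # elements drawn as (1/n) W(n, I) vs alternative scale 4I
  n <- 50
  p <- 5
  draws <- sample_wishart(diag(p), n, 200, seed = 55)
  mod_a <- mk_model(diag(p))
  mod_b <- mk_model(4 * diag(p), label = "B", id = "m2")
  signs <- vapply(draws, function(w) {
    e <- element_sample(as.matrix(w) / n, n, "A", "tmp")
    complete_score(e, mod_a, mod_b, mode = "literal") > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("transform_dataset scores every element without leakage", {
  a1 <- matrix(c(1, 0.2, 0.2, 1), 2)
  els <- list(
    element_sample(a1, 10, "A", "a1"),
    element_sample(2 * diag(2), 12, "A", "a2"),
    element_sample(diag(2), 10, "B", "b1"),
    element_sample(0.5 * diag(2), 14, "B", "b2")
  )
  sc <- transform_dataset(els)
  expect_equal(nrow(sc), 4L)
  expect_named(sc, c("element_id", "label", "complete_score",
                     "ratio_f1", "ratio_f2"))
  expect_identical(attr(sc, "classes"), c("A", "B"))
  # leakage audit by hand: a1's own-class model must be exactly a2's matrix
  mod_a <- estimate_scale_matrix(els[2], label = "A")
  mod_b <- estimate_scale_matrix(els[3:4], label = "B")
  by_hand <- score_ratio_vector(els[[1]], mod_a, mod_b)
  expect_equal(sc$complete_score[1], by_hand$complete_score)
  expect_equal(unname(unlist(sc[1, c("ratio_f1", "ratio_f2")])),
               unname(by_hand$per_feature))
})

test_that("transform_dataset enforces the two-class contract", {
  mk <- function(lab, id) element_sample(diag(2), 5, lab, id)
  expect_error(transform_dataset(list(mk("A", "a1"), mk("A", "a2"))),
               class = "class_too_small_error")
  expect_error(
    transform_dataset(list(mk("A", "a1"), mk("A", "a2"),
                           mk("B", "b1"), mk("B", "b2"),
                           mk("C", "c1"), mk("C", "c2"))),
    class = "more_than_two_classes_error"
  )
})

test_that("score tables round-trip through delimited text", {
  els <- make_two_class_elements(diag(3), 2 * diag(3), k = 3, seed = 41)
  sc <- transform_dataset(els)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(sc, path)
  back <- read_score_table(path)
  expect_equal(back$complete_score, sc$complete_score)
  expect_identical(names(back), names(sc))
})
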