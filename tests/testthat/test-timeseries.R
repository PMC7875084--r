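test_that("split_batches finds maximal constant-label runs", {
  x <- matrix(seq_len(12), ncol = 2)
  b <- split_batches(x, c(0, 0, 1, 1, 1, 0))
  expect_length(b, 3)
  expect_equal(vapply(b, function(bb) nrow(bb$data), integer(1)), c(2L, 3L, 1L))
  expect_equal(vapply(b, `[[`, "", "label"), c("0", "1", "0"))
  expect_equal(vapply(b, `[[`, 1L, "t_start"), c(0L, 2L, 5L))
  expect_equal(vapply(b, `[[`, 1L, "t_end"), c(2L, 5L, 6L))
  # concatenation reproduces the input
  expect_equal(unname(do.call(rbind, lapply(b, `[[`, "data"))), x)

  expect_length(split_batches(x, rep("z", 6)), 1)
  expect_length(split_batches(x[1:4, ], c(0, 1, 0, 1)), 4)
  expect_error(split_batches(x, c(0, 1)), class = "length_mismatch_error")
})

test_that("random label vectors are partitioned exactly", {
  set.seed(9)
  for (rep in 1:20) {
    t_len <- sample(5:40, 1)
    labels <- sample(c("a", "b", "c"), t_len, replace = TRUE)
    x <- matrix(rnorm(t_len * 2), ncol = 2)
    b <- split_batches(x, labels)
    expect_equal(sum(vapply(b, function(bb) nrow(bb$data), integer(1))), t_len)
    for (bb in b) {
      expect_length(unique(labels[(bb$t_start + 1):bb$t_end]), 1)
    }
  }
})

test_that("covariance uses divisor T on centered data", {
  # hand computation on a 4-point, 2-channel series
  x <- matrix(c(1, 2, 3, 6,
                2, 4, 6, 8), ncol = 2)
  b <- batch_series(x, "A")
  e <- batch_to_element(b, statistic = "covariance")
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(unname(as.matrix(e$matrix)), crossprod(xc) / 4)
  expect_identical(e$dof, 4L)
  e1 <- batch_to_element(b, statistic = "covariance", divisor = "n-1")
  expect_equal(unname(as.matrix(e1$matrix)), crossprod(xc) / 3)
})

test_that("correlation matrices have unit diagonal and bounded entries", {
  set.seed(33)
  x <- matrix(rnorm(60), ncol = 3) %*% chol(rand_spd(3))
  e <- batch_to_element(batch_series(x, "A"), statistic = "correlation")
  m <- as.matrix(e$matrix)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(abs(m) <= 1 + 1e-12))
  expect_equal(unname(m), unname(stats::cor(x)))
})

test_that("degenerate channels are rejected, collinear ones need a ridge", {
  x <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(batch_to_element(batch_series(x, "A"), statistic = "correlation"),
               class = "degenerate_channel_error")
  y <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(batch_to_element(batch_series(y, "A"), statistic = "correlation"),
               class = "not_positive_definite_error")
  e <- batch_to_element(batch_series(y, "A"), statistic = "correlation",
                        ridge = 1e-6)
  expect_s3_class(e, "element_sample")
})

test_that("batches shorter than the channel count are dropped or raise", {
  short <- batch_series(matrix(rnorm(3 * 5), nrow = 3), "A")
  expect_null(batch_to_element(short, min_length_policy = "drop"))
  expect_error(batch_to_element(short, min_length_policy = "error"),
               class = "batch_too_short_error")
  long <- batch_series(matrix(rnorm(20 * 2), nrow = 20), "B")
  res <- batches_to_elements(list(short, long))
  expect_length(res$elements, 1)
  expect_equal(res$n_dropped, 1L)
  expect_identical(res$dropped_ids, "batch_0001")
})

test_that("large Gaussian batches recover their covariance", {
  set.seed(71)
  x <- matrix(rnorm(100 * 3), ncol = 3)
  e <- batch_to_element(batch_series(x, "A"))
  expect_identical(e$dof, 100L)
  expect_lt(max(abs(as.matrix(e$matrix) - diag(3))), 0.5)
})

test_that("labeled series round-trip through delimited text and ARFF", {
  df <- data.frame(F7 = rnorm(20), T8 = rnorm(20),
                   state = rep(c("open", "closed"), each = 10))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  got <- read_labeled_series(csv, label_col = "state")
  expect_equal(unname(got$series), unname(as.matrix(df[1:2])))
  expect_equal(got$labels, df$state)

  arff <- withr::local_tempfile(fileext = ".arff")
  foreign::write.arff(df, arff)
  got2 <- read_labeled_series(arff)
  expect_equal(unname(got2$series), unname(as.matrix(df[1:2])), tolerance = 1e-6)
  expect_equal(got2$labels, df$state)
})

test_that("element sets round-trip through manifests and triangle tables", {
  els <- make_two_class_elements(diag(3), 0.5 * diag(3) + 0.2, k = 3, seed = 61)
  dir <- withr::local_tempdir()
  write_elements(els, dir)
  back <- read_elements(dir)
  expect_equal(lapply(back, function(e) as.matrix(e$matrix)),
               lapply(els, function(e) as.matrix(e$matrix)))
  expect_equal(vapply(back, `[[`, 1L, "dof"), vapply(els, `[[`, 1L, "dof"))

  tab <- elements_to_table(els)
  expect_equal(ncol(tab), 3 + 3 * 4 / 2)
  back2 <- table_to_elements(tab)
  expect_equal(lapply(back2, function(e) as.matrix(e$matrix)),
               lapply(els, function(e) as.matrix(e$matrix)))
  expect_equal(vapply(back2, `[[`, "", "label"),
               vapply(els, `[[`, "", "label"))
})
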