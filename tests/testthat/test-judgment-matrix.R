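test_that("construction and validation enforce the reciprocal-matrix invariants", {
  expect_s3_class(judgment_matrix(matrix(1, 3, 3)), "judgment_matrix")

  m <- rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1))
  expect_s3_class(judgment_matrix(m), "judgment_matrix")
  expect_s3_class(judgment_matrix(m, strict = TRUE), "judgment_matrix")

  bad <- rbind(c(1, 3), c(0.5, 1))
  expect_error(judgment_matrix(bad), "reciprocity.*\\(2,1\\)")
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(rbind(c(1, -2), c(-1/2, 1))), "non-positive")
  expect_error(judgment_matrix(rbind(c(2, 1), c(1, 1))), "diagonal")
  # 2.5 is reciprocal-consistent but not on the Saaty scale
  notsaaty <- rbind(c(1, 2.5), c(1/2.5, 1))
  expect_s3_class(judgment_matrix(notsaaty), "judgment_matrix")
  expect_error(judgment_matrix(notsaaty, strict = TRUE), "Saaty")
})

test_that("column normalization yields unit column sums", {
  expect_equal(column_normalize(judgment_matrix(matrix(1, 3, 3))),
               matrix(1/3, 3, 3), ignore_attr = TRUE)
  cn <- column_normalize(judgment_matrix(rbind(c(1, 3), c(1/3, 1))))
  expect_equal(cn, rbind(c(0.75, 0.75), c(0.25, 0.25)), ignore_attr = TRUE)

  set.seed(11)
  m <- make_consistent_matrix(random_weights(4), noise = 0.4)
  expect_equal(colSums(column_normalize(m)), rep(1, 4), ignore_attr = TRUE)
})

test_that("sum-product priority vector recovers consistent weights exactly", {
  expect_equal(priority_vector(judgment_matrix(matrix(1, 3, 3))),
               rep(1/3, 3), ignore_attr = TRUE)

  w <- c(0.6, 0.3, 0.1)
  m <- judgment_matrix(outer(w, w, "/"))
  expect_equal(priority_vector(m), w, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(priority_vector(m)), 1, tolerance = 1e-12)
})

test_that("priority vector agrees with the eigen-decomposition oracle on noisy matrices", {
  set.seed(21)
  for (i in 1:50) {
    m <- make_consistent_matrix(random_weights(5), noise = stats::runif(1, 0, 0.3))
    expect_lt(max(abs(priority_vector(m) - eigen_priority(m))), 0.02)
  }
})

test_that("priority vector is permutation-equivariant", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    m <- make_consistent_matrix(random_weights(n), noise = 0.25)
    p <- sample(n)
    mp <- judgment_matrix(unclass(m)[p, p])
    expect_equal(as.numeric(priority_vector(mp)),
                 as.numeric(priority_vector(m)[p]), tolerance = 1e-12)
  }
})

test_that("lambda_max equals n for consistent matrices and matches the eigen oracle otherwise", {
  m1 <- judgment_matrix(matrix(1, 3, 3))
  expect_equal(lambda_max(m1), 3, tolerance = 1e-12)

  w <- c(0.6, 0.3, 0.1)
  expect_equal(lambda_max(judgment_matrix(outer(w, w, "/"))), 3,
               tolerance = 1e-9)

  m <- judgment_matrix(rbind(c(1, 1, 3), c(1, 1, 1), c(1/3, 1, 1)))
  expect_equal(lambda_max(m), eigen_lambda_max(m), tolerance = 1e-3)

  expect_error(lambda_max(m1, w = c(0, 0.5, 0.5)), "not positive")
})

test_that("consistency test computes CI/CR and applies the CR < 0.1 rule", {
  w <- c(0.5, 0.3, 0.2)
  rep1 <- consistency(judgment_matrix(outer(w, w, "/")))
  expect_equal(rep1$ci, 0, tolerance = 1e-9)
  expect_equal(rep1$cr, 0, tolerance = 1e-9)
  expect_true(rep1$passed)
  expect_equal(rep1$ri, 0.58)

  # order-2 reciprocal matrices are always consistent; RI = 0 must not
  # produce a division by zero
  rep2 <- consistency(judgment_matrix(rbind(c(1, 7), c(1/7, 1))))
  expect_equal(rep2$cr, 0)
  expect_true(rep2$passed)

  # a maximally contradictory cycle must fail
  contra <- judgment_matrix(rbind(c(1, 9, 1/9), c(1/9, 1, 9), c(9, 1/9, 1)))
  expect_false(consistency(contra)$passed)
  expect_gt(consistency(contra)$cr, 0.1)
  expect_equal(consistency(contra)$cr, eigen_cr(contra), tolerance = 1e-2)
})

test_that("RI lookup matches the tabulated random index and rejects larger orders", {
  expect_equal(vapply(1:9, random_index, numeric(1)),
               c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45))
  expect_error(random_index(10), "1\\.\\.9")
  expect_error(random_index(0), "positive integer")
})

test_that("lambda_max >= n, with equality only for consistent matrices", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    w <- random_weights(n)
    cons <- make_consistent_matrix(w, noise = 0)
    expect_equal(lambda_max(cons), n, tolerance = 1e-9)
    expect_equal(consistency(cons)$ci, 0, tolerance = 1e-9)
    pert <- make_consistent_matrix(w, noise = 0.4)
    expect_gte(lambda_max(pert), n - 1e-9)
    if (consistency(pert)$ci > 1e-6) expect_gt(lambda_max(pert), n)
  }
})

test_that("judgment matrices round-trip through CSV and JSON", {
  m <- judgment_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1)),
                       labels = c("soil", "crop", "amendment"))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(unclass(m)), csv)
  m2 <- read_judgment_matrix(csv)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(m2), c("soil", "crop", "amendment"))

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(entries = unclass(m), labels = rownames(m)), js,
                       digits = NA)
  m3 <- read_judgment_matrix(js)
  expect_equal(unclass(m3), unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
})
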