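test_that("Little's test reports 'not applicable' on complete data", {
  r <- littles_mcar_test(data.frame(a = 1:10, b = rnorm(10)))
  expect_false(r$applicable)
  expect_equal(r$df, 0L)
  expect_output(print(r), "not applicable")
})

test_that("Little's statistic is invariant to affine rescaling", {
  d <- mvn_mcar_table(500, 0.15, seed = 8)
  r1 <- littles_mcar_test(d)
  d2 <- d
  d2$v1 <- d2$v1 * 1000 + 5
  d2$v3 <- -d2$v3 / 7
  r2 <- littles_mcar_test(d2)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-4)
  expect_equal(r1$df, r2$df)
})

test_that("Little's test rejects strong MAR missingness", {
  reject <- vapply(1:30, function(s) {
    d <- mvn_mcar_table(2000, 0.2, seed = 1000 + s, mar_on = "v2", mar_coef = 1.5)
    littles_mcar_test(d)$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})

test_that("chained_impute is a no-op copier on complete data, and reproducible", {
  d <- data.frame(y = rbinom(50, 1, 0.4), x = rnorm(50))
  imp <- chained_impute(d, m = 3, n_iterations = 2, seed = 9)
  expect_length(imp$imputations, 3)
  for (k in 1:3) expect_identical(imp$imputations[[k]], d)

  set.seed(31)
  d$y[sample(50, 10)] <- NA
  i1 <- chained_impute(d, m = 2, n_iterations = 5, seed = 11)
  i2 <- chained_impute(d, m = 2, n_iterations = 5, seed = 11)
  expect_identical(i1$imputations, i2$imputations)
  i3 <- chained_impute(d, m = 2, n_iterations = 5, seed = 12)
  expect_false(identical(i1$imputations, i3$imputations))

  expect_error(chained_impute(data.frame(a = c(NA, NA), b = 1:2)),
               "zero observed values")
})

test_that("imputation never alters observed cells, across variable types", {
  set.seed(77)
  n <- 400
  d <- data.frame(
    bin = rbinom(n, 1, 0.3),
    cont = rnorm(n, 10, 2),
    cat = factor(sample(c("a", "b", "c"), n, replace = TRUE)))
  for (v in names(d)) d[[v]][sample(n, 40)] <- NA
  imp <- chained_impute(d, m = 2, n_iterations = 3, seed = 5)
  for (k in 1:2) {
    comp <- imp$imputations[[k]]
    expect_false(anyNA(comp))
    for (v in names(d)) {
      obs <- !is.na(d[[v]])
      expect_identical(comp[[v]][obs], d[[v]][obs])
    }
    # pmm donates observed values only
    expect_true(all(comp$cont %in% d$cont))
  }
})

test_that("MCAR imputation recovers the full-data prevalence", {
  aset <- complete_aset(4000, seed = 51)
  full_prev <- mean(aset$Y)
  d <- aset[c("X", "M1", "M2", "Y", attr(aset, "confounders"))]
  set.seed(13)
  d$Y[runif(4000) < 0.1] <- NA
  imp <- chained_impute(d, m = 3, n_iterations = 5, seed = 17)
  pooled <- mean(vapply(imp$imputations, function(t) mean(t$Y), numeric(1)))
  se <- sqrt(full_prev * (1 - full_prev) / 4000)
  expect_lt(abs(pooled - full_prev), 3 * se)
})

test_that("compare_imputed flags nothing under completeness, distortion under MNAR", {
  d <- data.frame(a = rnorm(100), b = rbinom(100, 1, 0.5))
  imp <- chained_impute(d, m = 2, n_iterations = 2, seed = 3)
  diag <- compare_imputed(d, imp)
  expect_true(all(diag$std_diff == 0))

  # adversarial MNAR: y strongly predicted by x, missing when y is large
  set.seed(99)
  n <- 4000
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.5)
  dm <- data.frame(x = x, y = y)
  dm$y[plogis(-1.5 + 2 * y) > runif(n)] <- NA
  impm <- chained_impute(dm, m = 3, n_iterations = 5, seed = 7)
  diagm <- compare_imputed(dm, impm)
  expect_gt(max(abs(diagm$std_diff), na.rm = TRUE), 0.1)
})
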