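test_that("OECD equivalisation follows the modified scale", {
  expect_equal(oecd_equivalise(20000, n_adults = 1), 20000)
  expect_equal(oecd_equivalise(21000, n_adults = 2, n_children_u14 = 2), 10000)
  expect_equal(oecd_equivalise(0, n_adults = 3, n_children_u14 = 4), 0)
  expect_error(oecd_equivalise(1000, n_adults = 0), "empty household")
  expect_error(oecd_equivalise(-5, n_adults = 1), "non-negative")

  # homogeneity: scaling income scales the result
  set.seed(1)
  for (i in 1:20) {
    inc <- runif(1, 0, 6e4); k <- runif(1, 0.1, 9)
    na_ <- sample(1:3, 1); no <- sample(0:2, 1); nc <- sample(0:4, 1)
    expect_equal(oecd_equivalise(k * inc, na_, no, nc),
                 k * oecd_equivalise(inc, na_, no, nc))
  }
})

test_that("quintile_flag reproduces brute-force rankings and handles ties", {
  expect_equal(which(quintile_flag(1:10, "bottom_two") == 1), 1:4)
  expect_equal(which(quintile_flag(1:10, "bottom_one") == 1), 1:2)
  expect_equal(which(quintile_flag(1:10, "top_one") == 1), 9:10)

  expect_warning(f <- quintile_flag(rep(3, 8), "bottom_two"), "identical")
  expect_true(all(f == 0))

  # ties at the cut are flagged (40% + tie mass)
  v <- c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10)
  expect_equal(sum(quintile_flag(v, "bottom_two")), 4)  # F(2)=0.4: all 2s in
  v2 <- c(1, 2, 2, 2, 2, 6, 7, 8, 9, 10)
  expect_equal(sum(quintile_flag(v2, "bottom_two")), 5) # tie mass spills over

  # missing in -> missing out
  f3 <- quintile_flag(c(NA, 1:9), "bottom_two")
  expect_true(is.na(f3[1]) && !anyNA(f3[-1]))

  # weighted cut against a brute-force weighted ECDF
  vals <- c(10, 20, 30, 40, 50); w <- c(5, 1, 1, 1, 2)
  # Fw: 0.5, 0.6, 0.7, 0.8, 1.0 -> 0.4-cut at 10, flags only the 10
  expect_equal(as.integer(quintile_flag(vals, "bottom_two", weights = w)),
               c(1L, 0L, 0L, 0L, 0L))
  expect_error(quintile_flag(c(1, 2, 3), "bottom_two"), "at least 5")
})

test_that("SDQ banding partitions 0-40 at 14 and 17", {
  expect_equal(as.character(sdq_band(c(13, 14, 16, 17))),
               c("normal", "borderline", "borderline", "abnormal"))
  expect_equal(attr(sdq_band(c(16, 17, NA)), "flag"), c(0L, 1L, NA))
  all_bands <- sdq_band(0:40)
  expect_false(anyNA(all_bands))
  expect_equal(as.integer(table(all_bands)), c(14, 3, 24))
  expect_error(sdq_band(41), "range")
  expect_error(sdq_band(-1), "range")
})

test_that("dass_flag sums six items and flags the top quintile", {
  # constructed sample: 20% have sum >= 12
  sums <- c(rep(0, 4), rep(5, 2), rep(8, 2), 12, 13)
  items <- t(vapply(sums, function(s) {
    v <- integer(6); left <- as.integer(s)
    for (j in 1:6) { v[j] <- min(3L, left); left <- left - v[j] }
    v
  }, integer(6)))
  f <- dass_flag(items)
  expect_equal(as.integer(f), c(rep(0L, 8), 1L, 1L))
  expect_equal(f[9], 1L)    # child at the cut (sum 12) is flagged

  items2 <- items; items2[1, 3] <- NA
  expect_true(is.na(dass_flag(items2)[1]))
  expect_equal(as.integer(dass_flag(items2)[-1]), as.integer(f[-1]))
  expect_error(dass_flag(items[, 1:5]), "six")
  bad <- items; bad[2, 1] <- 4
  expect_error(dass_flag(bad), "0-3")
})

test_that("cprs_flag is low closeness OR high conflict", {
  clo <- c(35, 7, 20, 18, 25, 30, 33, 28, 29, 31)
  con <- c(8, 10, 12, 14, 40, 9, 11, 13, 15, 16)
  f <- cprs_flag(clo, con)
  expect_equal(f[1], 0L)          # max closeness, min conflict
  expect_equal(f[2], 1L)          # bottom-quintile closeness, low conflict
  expect_equal(f[5], 1L)          # top-quintile conflict, median closeness
  expect_true(is.na(cprs_flag(c(NA, clo), c(NA, con))[1]))
})

test_that("derive_analysis_set matches hand-derived flags on the toy cohort", {
  aset <- derive_analysis_set(toy_cohort(), cutpoints = toy_cutpoints())
  exp <- toy_expected()
  for (v in names(exp)) expect_equal(aset[[v]], exp[[v]], info = v)
  expect_equal(aset$w, toy_cohort()$weight)
  # row with missing income: X missing, everything else derived
  expect_true(is.na(aset$X[3]) && !is.na(aset$M1[3]) && !is.na(aset$Y[3]))
  expect_error(derive_analysis_set(toy_cohort()[, -2]), "missing columns")
})

test_that("derived flags round-trip the simulator latents", {
  p <- quick_params(5000, seed = 21)
  co <- generate_cohort(p, inject_missing = FALSE)
  aset <- derive_analysis_set(co, cutpoints = attr(co, "cutpoints"))
  lat <- attr(co, "latents")
  expect_equal(aset$X, lat$X)
  expect_equal(aset$M1, lat$M1)
  expect_equal(aset$M2, lat$M2)
  expect_equal(aset$Y, lat$Y)
})

test_that("the below-60%-median alternative exposure rule works", {
  co <- generate_cohort(quick_params(2000, seed = 31), inject_missing = FALSE)
  aset <- derive_analysis_set(co, income_rule = "below_60pct_median")
  eq <- oecd_equivalise(co$hh_income, co$n_adults, co$n_other_14plus,
                        co$n_children_u14)
  expect_equal(aset$X, as.integer(eq < 0.6 * median(eq)))
})
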