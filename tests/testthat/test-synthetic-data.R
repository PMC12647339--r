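test_that("structural_params validates its inputs", {
  expect_error(structural_params(n_children = 0), "n_children")
  expect_error(structural_params(conf_prevalences = c(
    low_educ = 1.2, low_mat_age = .04, unemployed = .3, children_4plus = .04,
    one_parent = .14, ethnic_minority = .03)), "prevalences")
  p <- structural_params()
  p$missing_rates["sdq_total"] <- 1
  expect_error(do.call(structural_params, p[c("n_children", "seed", "conf_prevalences",
    "alpha_X", "alpha_M1", "alpha_M2", "alpha_Y", "raw_scale_params",
    "missing_rates")]), "missing rates")
  bad <- structural_params()$alpha_Y
  bad["X"] <- Inf
  expect_error(structural_params(alpha_Y = bad), "finite")
})

test_that("generation is deterministic under a fixed seed", {
  p <- structural_params(n_children = 400, seed = 99)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
})

test_that("calibrated cohort hits the published exposure prevalence", {
  aset <- complete_aset(50000, seed = 101)
  p_hat <- mean(aset$X)
  se <- sqrt(0.389 * (1 - 0.389) / 50000)
  expect_lt(abs(p_hat - 0.389), 3 * se)

  # stratum prevalences of mediators and outcome, generous 4-SE bands
  tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)
  n1 <- sum(aset$X == 1); n0 <- sum(aset$X == 0)
  expect_lt(abs(mean(aset$M1[aset$X == 1]) - 0.306), tol(0.306, n1))
  expect_lt(abs(mean(aset$M1[aset$X == 0]) - 0.184), tol(0.184, n0))
  expect_lt(abs(mean(aset$M2[aset$X == 1]) - 0.406), tol(0.406, n1))
  expect_lt(abs(mean(aset$Y[aset$X == 0]) - 0.027), tol(0.027, n0))
})

test_that("removing every X path (and Y's confounder load) kills the crude X-Y association", {
  p <- params_zero_paths(50000, seed = 7)
  p$alpha_Y[names(p$conf_prevalences)] <- 0   # Y independent of everything
  co <- generate_cohort(p, inject_missing = FALSE)
  lat <- attr(co, "latents")
  a <- sum(lat$X == 1 & lat$Y == 1); b <- sum(lat$X == 1 & lat$Y == 0)
  c_ <- sum(lat$X == 0 & lat$Y == 1); d <- sum(lat$X == 0 & lat$Y == 0)
  log_or <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_lt(abs(log_or), 3 * se)
})

test_that("inject_missingness honours rates and mechanisms", {
  p0 <- quick_params(300, seed = 5)
  co <- generate_cohort(p0, inject_missing = FALSE)
  expect_identical(inject_missingness(co, p0), co)   # all rates zero

  rates <- zero_rates(); rates["sdq_total"] <- 0.10
  p <- structural_params(n_children = 20000, seed = 5, missing_rates = rates)
  com <- inject_missingness(generate_cohort(p, inject_missing = FALSE), p, seed = 77)
  frac <- mean(is.na(com$sdq_total))
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 20000))

  pm <- structural_params(n_children = 20000, seed = 6, missing_rates = rates,
                          missing_mechanism = "MAR", missing_coef = 1.0)
  com2 <- inject_missingness(generate_cohort(pm, inject_missing = FALSE), pm, seed = 78)
  tab <- table(miss = is.na(com2$sdq_total), onep = com2$one_parent)
  expect_lt(stats::chisq.test(tab)$p.value, 0.01)

  bad <- pm; bad$missing_mechanism <- "weird"
  expect_error(inject_missingness(com2, bad), "mechanism")
})

test_that("oracle_effects matches the closed-form enumeration oracle", {
  p <- quick_params(100, seed = 1)
  truth <- analytic_effects(p)
  # frozen reference of the calibrated world (from the same enumeration)
  expect_equal(unname(exp(truth)),
               c(2.1094, 1.0387, 1.0239, 1.0636, 2.2435), tolerance = 1e-4)
  oe <- oracle_effects(p, n_mc = 2e5, seed = 42)
  for (e in names(truth)) {
    expect_lt(abs(oe$log_or[[e]] - truth[[e]]), 3 * oe$mc_se[[e]] + 1e-3)
  }
})

test_that("oracle nulls: zero direct path and zero mediated paths", {
  p1 <- quick_params(100, seed = 2)
  p1$alpha_Y["X"] <- 0
  oe1 <- oracle_effects(p1, n_mc = 1e5, seed = 3)
  expect_lt(abs(log(oe1$or_nde)), 3 * oe1$mc_se[["nde"]] + 1e-3)

  p2 <- quick_params(100, seed = 2)
  p2$alpha_M1["X"] <- 0; p2$alpha_M2["X"] <- 0
  oe2 <- oracle_effects(p2, n_mc = 1e5, seed = 3)
  expect_lt(abs(log(oe2$or_nie_joint)), 3 * oe2$mc_se[["nie_joint"]] + 1e-3)
})

test_that("decomposition closure holds exactly for arbitrary parameters", {
  for (s in 1:5) {
    p <- quick_params(100, seed = s)
    p$alpha_Y["X"] <- runif(1, -1, 1.5)
    p$alpha_M1["X"] <- runif(1, -1, 1)
    p$alpha_M2["X"] <- runif(1, -1, 1)
    oe <- oracle_effects(p, n_mc = 5000, seed = s)
    expect_equal(oe$or_te, oe$or_nde * oe$or_nie_joint, tolerance = 1e-12)
  }
})

test_that("or_nde is monotone in the direct-path coefficient", {
  vals <- vapply(c(0, 0.5, 1.0), function(bx) {
    p <- quick_params(100, seed = 4)
    p$alpha_Y["X"] <- bx
    oracle_effects(p, n_mc = 2e5, seed = 11)$or_nde
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
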