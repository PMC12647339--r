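# shared large calibrated cohort for the coefficient-recovery checks
aset50 <- complete_aset(50000, seed = 301)
true_params <- quick_params(50000, 301)

test_that("working models recover null and true coefficients", {
  # independent everything: all non-intercept coefficients near zero
  set.seed(8)
  n <- 20000
  null_d <- data.frame(X = rbinom(n, 1, .4), M1 = rbinom(n, 1, .2),
                       M2 = rbinom(n, 1, .35), Y = rbinom(n, 1, .1),
                       z1 = rbinom(n, 1, .3), z2 = rbinom(n, 1, .5), w = 1)
  attr(null_d, "confounders") <- c("z1", "z2")
  om0 <- fit_outcome_imputation_model(null_d)
  z <- (om0$coefficients / om0$se)[-1]
  expect_true(all(abs(z) < 3))
  mm0 <- fit_mediator_model(null_d)
  expect_true(all(abs((mm0$coefficients / mm0$se)[-1]) < 3))

  # recovery of the structural X coefficients on the calibrated world
  om <- fit_outcome_imputation_model(aset50)
  expect_lt(abs(om$coefficients[["X"]] - true_params$alpha_Y[["X"]]),
            3 * om$se[["X"]])
  mm <- fit_mediator_model(aset50)
  expect_lt(abs(mm$coefficients[["X"]] - true_params$alpha_M1[["X"]]),
            3 * mm$se[["X"]])
})

test_that("saturated fits reproduce cell means exactly", {
  d <- onec_aset(2000, seed = 12)
  sp <- natural_model_spec(saturated_models = TRUE, B = 1)
  om <- fit_outcome_imputation_model(d, sp)
  mm <- fit_mediator_model(d, sp)
  cells <- expand.grid(X = 0:1, M1 = 0:1, M2 = 0:1, z = 0:1)
  for (i in seq_len(nrow(cells))) {
    sel <- d$X == cells$X[i] & d$M1 == cells$M1[i] & d$M2 == cells$M2[i] &
      d$z == cells$z[i]
    if (!any(sel)) next
    pred <- om$predict(cells$X[i], cells$M1[i], cells$M2[i],
                       matrix(cells$z[i], 1, 1, dimnames = list(NULL, "z")))
    expect_equal(unname(pred), mean(d$Y[sel]), tolerance = 1e-7)
  }
  for (x in 0:1) for (zz in 0:1) {
    sel <- d$X == x & d$z == zz
    pred <- mm$predict(x, matrix(zz, 1, 1, dimnames = list(NULL, "z")))
    expect_equal(unname(pred), mean(d$M1[sel]), tolerance = 1e-7)
  }
})

test_that("expansion degenerates correctly and pins x2 to observed exposure", {
  d <- onec_aset(300, seed = 13)
  # outcome model that ignores M1: expectations identical across x1
  om_nom1 <- structure(list(confounders = "z", predict = function(x, m1, m2, C)
    plogis(-1 + 0.5 * x + 0.3 * m2 + 0.2 * C[, "z"])), class = "outcome_model")
  mm <- fit_mediator_model(d, natural_model_spec(B = 1))
  ex <- expand_and_impute(d, om_nom1, mm)
  expect_equal(nrow(ex), 4 * nrow(d))
  expect_equal(ex$x2, rep(d$X, 4))             # identification constraint
  e00 <- ex$eh[ex$x0 == 0 & ex$x1 == 0]
  e01 <- ex$eh[ex$x0 == 0 & ex$x1 == 1]
  expect_equal(e00, e01, tolerance = 1e-12)

  # degenerate mediator: P(M1=1)=0 collapses the mixture
  mm0 <- structure(list(confounders = "z", predict = function(x, C)
    rep(0, nrow(C))), class = "mediator_model")
  om <- fit_outcome_imputation_model(d, natural_model_spec(B = 1))
  ex0 <- expand_and_impute(d, om, mm0)
  direct <- om$predict(ex0$x0, 0, d$M2[ex0$row_id],
                       matrix(d$z[ex0$row_id], ncol = 1,
                              dimnames = list(NULL, "z")))
  expect_equal(ex0$eh, direct, tolerance = 1e-12)

  d_na <- d; d_na$M2[3] <- NA
  expect_error(expand_and_impute(d_na, om, mm), "missing flags")
})

test_that("natural model preserves nulls at large n", {
  p_null_med <- quick_params(50000, seed = 71)
  p_null_med$alpha_M1["X"] <- 0; p_null_med$alpha_M2["X"] <- 0
  fit1 <- natural_effects(complete_aset(50000, 71, p_null_med))
  expect_gt(fit1$or_nie_joint, 0.97); expect_lt(fit1$or_nie_joint, 1.03)

  p_null_dir <- quick_params(50000, seed = 72)
  p_null_dir$alpha_Y["X"] <- 0
  fit2 <- natural_effects(complete_aset(50000, 72, p_null_dir))
  expect_gt(fit2$or_nde, 0.95); expect_lt(fit2$or_nde, 1.05)
})

test_that("proportion mediated follows the odds-ratio formula", {
  expect_equal(proportion_mediated(1.7, 1), 0)
  expect_equal(proportion_mediated(1, 2), 1)
  expect_equal(round(proportion_mediated(2.02, 1.06), 4), 0.1062)
  und <- proportion_mediated(2, 0.5)      # denominator exactly zero
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
})

test_that("bootstrap CIs: constants give zero width, seeds give determinism", {
  aset <- complete_aset(400, seed = 81)
  const <- function(d) c(nde = 0.1, nie_m1 = 0.2, nie_m2 = 0.3,
                         nie_joint = 0.5, te = 0.6)
  sp <- natural_model_spec(B = 20, seed = 5)
  bs <- bootstrap_cis(aset, sp, estimator = const)
  expect_equal(unname(bs$ci[, "low"]), unname(bs$ci[, "high"]))
  expect_equal(unname(bs$ci["nde", "low"]), exp(0.1))

  b1 <- bootstrap_cis(aset, sp)
  b2 <- bootstrap_cis(aset, sp)
  expect_identical(b1$ci, b2$ci)

  always_fail <- function(d) stop("boom")
  expect_error(bootstrap_cis(aset, sp, estimator = always_fail), "replicates")
})

test_that("pooling over imputations averages theta on the log-odds scale", {
  f1 <- seqmediate:::new_natural_effects_fit(c(`(Intercept)` = -2, x0 = 0.6,
                                               x1 = 0.10, x2 = 0.30))
  f2 <- seqmediate:::new_natural_effects_fit(c(`(Intercept)` = -2, x0 = 0.8,
                                               x1 = 0.20, x2 = 0.10))
  pooled <- pool_over_imputations(list(f1, f2))
  expect_equal(pooled$theta[["x0"]], 0.7)
  expect_equal(pooled$or_te, pooled$or_nde * pooled$or_nie_joint)
  same <- pool_over_imputations(list(f1, f1, f1))
  expect_equal(same$log_or, f1$log_or)
  f3 <- seqmediate:::new_natural_effects_fit(c(`(Intercept)` = -2, x0 = 0.8,
                                               x1 = 0.2, x2 = 0.1, zz = 1))
  expect_error(pool_over_imputations(list(f1, f3)), "mismatched")
})

test_that("MI-pooled estimates track the complete-data estimates", {
  aset <- complete_aset(4000, seed = 91)
  sp <- natural_model_spec(B = 40, seed = 2)
  complete_fit <- natural_effects(aset, sp)
  bs <- bootstrap_cis(aset, sp)
  sd_nde <- sd(bs$replicates[, "nde"], na.rm = TRUE)

  degraded <- aset
  set.seed(14)
  degraded$Y[runif(4000) < 0.1] <- NA
  mi_fit <- natural_effects_mi(degraded, sp, m = 5, n_iterations = 5)
  expect_lt(abs(mi_fit$log_or[["nde"]] - complete_fit$log_or[["nde"]]),
            3 * sd_nde)
  expect_equal(mi_fit$or_te, mi_fit$or_nde * mi_fit$or_nie_joint)
  expect_true(all(mi_fit$ci[, "low"] <= mi_fit$ci[, "high"]))
})
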