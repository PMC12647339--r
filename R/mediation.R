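#' Specification of the natural-effects model
#'
#' Options for the imputation-based natural-effects estimator: which
#' confounders enter every working model, whether exposure--mediator or
#' mediator--mediator interaction terms enter the outcome imputation model
#' (both off by default, so natural-model odds ratios transport cleanly),
#' the bootstrap size and seed, and the confidence level.
#'
#' @param confounders character vector of confounder column names, or
#'   `NULL` to take `attr(analysis_set, "confounders")`.
#' @param exposure_mediator_interactions include `X:M1` and `X:M2` in the
#'   outcome imputation model.
#' @param mediator_interaction include `M1:M2` in the outcome model.
#' @param saturated_models fit fully factorial (saturated) working models,
#'   interacting exposure, mediators and every confounder -- used for
#'   small-instance equivalence with the non-parametric g-formula.
#' @param B bootstrap replicates (default 1000).
#' @param seed master seed for bootstrap / imputation streams.
#' @param level confidence level (default 0.95).
#' @return Object of class `natural_model_spec`.
#' @export
natural_model_spec <- function(confounders = NULL,
                               exposure_mediator_interactions = FALSE,
                               mediator_interaction = FALSE,
                               saturated_models = FALSE,
                               B = 1000, seed = 1L, level = 0.95) {
  stopifnot(B >= 1, level > 0, level < 1)
  structure(list(confounders = confounders,
                 exposure_mediator_interactions = exposure_mediator_interactions,
                 mediator_interaction = mediator_interaction,
                 saturated_models = saturated_models,
                 B = as.integer(B), seed = as.integer(seed), level = level),
            class = "natural_model_spec")
}

spec_confounders <- function(analysis_set, spec) {
  cf <- spec$confounders
  if (is.null(cf)) cf <- attr(analysis_set, "confounders")
  if (is.null(cf)) cf <- setdiff(names(analysis_set),
                                 c("child_id", "X", "M1", "M2", "Y", "w"))
  cf
}

#' Outcome imputation model
#'
#' Weighted logistic regression of `Y` on `X`, `M1`, `M2` and the
#' confounders (plus any interaction terms the model spec requests), used to
#' impute counterfactual outcome expectations.  Separation triggers a
#' weakly penalised fallback with a warning.
#'
#' @param analysis_set complete (or singly imputed) `analysis_set`.
#' @param spec a [natural_model_spec()].
#' @return Object of class `outcome_model`: coefficients and a
#'   `predict(x, m1, m2, Cmat)` function returning `P(Y=1 | x, m1, m2, c)`.
#' @export
fit_outcome_imputation_model <- function(analysis_set, spec = natural_model_spec()) {
  cf <- spec_confounders(analysis_set, spec)
  d <- analysis_set
  if (anyNA(d[c("X", "M1", "M2", "Y", cf)])) {
    stop("analysis set contains missing flags; impute upstream first")
  }
  if (isTRUE(spec$saturated_models)) {
    form <- stats::as.formula(paste("~", paste(c("X * M1 * M2", cf), collapse = " * ")))
    Xd <- stats::model.matrix(form, data = d)
    fit <- fit_logit(Xd, d$Y, d$w)
    beta <- fit$coefficients
    names(beta) <- colnames(Xd)
    beta[is.na(beta)] <- 0   # aliased (empty-cell) terms contribute nothing
    vc <- logit_vcov(fit, Xd, d$w)
    predictor <- function(x, m1, m2, Cmat) {
      nd <- data.frame(X = x, M1 = m1, M2 = m2, as.data.frame(Cmat))
      stats::plogis(drop(stats::model.matrix(form, data = nd) %*% beta))
    }
  } else {
    form <- NULL
    Cmat <- as.matrix(d[cf])
    Xd <- cbind(`(Intercept)` = 1, X = d$X, M1 = d$M1, M2 = d$M2, Cmat)
    if (spec$exposure_mediator_interactions) {
      Xd <- cbind(Xd, `X:M1` = d$X * d$M1, `X:M2` = d$X * d$M2)
    }
    if (spec$mediator_interaction) Xd <- cbind(Xd, `M1:M2` = d$M1 * d$M2)
    fit <- fit_logit(Xd, d$Y, d$w)
    beta <- fit$coefficients
    names(beta) <- colnames(Xd)
    beta[is.na(beta)] <- 0
    vc <- logit_vcov(fit, Xd, d$w)
    bC <- beta[cf]
    predictor <- function(x, m1, m2, Cmat) {
      lp <- beta[["(Intercept)"]] + beta[["X"]] * x + beta[["M1"]] * m1 +
        beta[["M2"]] * m2 + drop(Cmat %*% bC)
      if ("X:M1" %in% names(beta)) lp <- lp + beta[["X:M1"]] * x * m1
      if ("X:M2" %in% names(beta)) lp <- lp + beta[["X:M2"]] * x * m2
      if ("M1:M2" %in% names(beta)) lp <- lp + beta[["M1:M2"]] * m1 * m2
      stats::plogis(lp)
    }
  }
  structure(list(coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
                 formula = form, confounders = cf, predict = predictor),
            class = "outcome_model")
}

#' First-mediator model
#'
#' Weighted logistic regression of `M1` on `X` and the confounders,
#' supplying `P(M1 = m1 | x, c)` for the counterfactual expansion.
#'
#' @inheritParams fit_outcome_imputation_model
#' @return Object of class `mediator_model` with a `predict(x, Cmat)`
#'   function returning `P(M1=1 | x, c)`.
#' @export
fit_mediator_model <- function(analysis_set, spec = natural_model_spec()) {
  cf <- spec_confounders(analysis_set, spec)
  d <- analysis_set
  if (anyNA(d[c("X", "M1", cf)])) {
    stop("analysis set contains missing flags; impute upstream first")
  }
  if (isTRUE(spec$saturated_models)) {
    form <- stats::as.formula(paste("~", paste(c("X", cf), collapse = " * ")))
    Xd <- stats::model.matrix(form, data = d)
    fit <- fit_logit(Xd, d$M1, d$w)
    beta <- fit$coefficients
    names(beta) <- colnames(Xd)
    beta[is.na(beta)] <- 0
    vc <- logit_vcov(fit, Xd, d$w)
    predictor <- function(x, Cmat) {
      nd <- data.frame(X = x, as.data.frame(Cmat))
      stats::plogis(drop(stats::model.matrix(form, data = nd) %*% beta))
    }
  } else {
    form <- NULL
    Cmat <- as.matrix(d[cf])
    Xd <- cbind(`(Intercept)` = 1, X = d$X, Cmat)
    fit <- fit_logit(Xd, d$M1, d$w)
    beta <- fit$coefficients
    names(beta) <- colnames(Xd)
    beta[is.na(beta)] <- 0
    vc <- logit_vcov(fit, Xd, d$w)
    bC <- beta[cf]
    predictor <- function(x, Cmat) {
      stats::plogis(beta[["(Intercept)"]] + beta[["X"]] * x + drop(Cmat %*% bC))
    }
  }
  structure(list(coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
                 formula = form, confounders = cf, predict = predictor),
            class = "mediator_model")
}

#' Counterfactual data expansion with imputed outcome expectations
#'
#' Expands every child to the four counterfactual index settings
#' `(x0, x1) in {0,1}^2`, with the second-mediator index `x2` pinned to the
#' child's observed exposure (the identification constraint of the
#' sequential design), and imputes the counterfactual outcome expectation
#' `E = sum_{m1} P(M1 = m1 | x1, c) * P(Y = 1 | x0, m1, m2_obs, c)`.
#' Survey weights are carried unchanged.
#'
#' @param analysis_set complete `analysis_set`.
#' @param outcome_model from [fit_outcome_imputation_model()].
#' @param mediator_model from [fit_mediator_model()].
#' @return data.frame of class `expanded_records`: `row_id`, `x0`, `x1`,
#'   `x2`, `eh` (imputed expectation), `w` and the confounder columns.
#' @export
expand_and_impute <- function(analysis_set, outcome_model, mediator_model) {
  cf <- outcome_model$confounders
  d <- analysis_set
  if (anyNA(d[c("X", "M1", "M2", "Y", cf)])) {
    stop("analysis set contains missing flags; impute upstream first")
  }
  Cmat <- as.matrix(d[cf])
  n <- nrow(d)
  blocks <- expand.grid(x0 = 0:1, x1 = 0:1)
  p1_by_x1 <- list(`0` = mediator_model$predict(0, Cmat),
                   `1` = mediator_model$predict(1, Cmat))
  eh <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    x0 <- blocks$x0[i]
    p1 <- p1_by_x1[[as.character(blocks$x1[i])]]
    (1 - p1) * outcome_model$predict(x0, 0, d$M2, Cmat) +
      p1 * outcome_model$predict(x0, 1, d$M2, Cmat)
  }), use.names = FALSE)
  rep4 <- rep(seq_len(n), nrow(blocks))
  out <- data.frame(row_id = rep4,
                    x0 = rep(blocks$x0, each = n), x1 = rep(blocks$x1, each = n),
                    x2 = d$X[rep4], eh = eh, w = d$w[rep4])
  out <- cbind(out, Cmat[rep4, , drop = FALSE])
  attr(out, "confounders") <- cf
  class(out) <- c("expanded_records", "data.frame")
  out
}

#' Fit the natural-effects model
#'
#' Weighted fractional-response logistic fit of the imputed counterfactual
#' expectation on the three exposure indices and the confounders:
#' `logit E(Y(x0, M1(x1), M2(x2, .))) = th0 + th1 x0 + th2 x1 + th3 x2 + C`.
#' By construction `OR_NDE = exp(th1)`, `OR_NIE(M1) = exp(th2)`,
#' `OR_NIE(M2) = exp(th3)`, `OR_NIE(joint) = exp(th2 + th3)` and
#' `OR_TE = exp(th1 + th2 + th3)`, so the decomposition
#' `TE = NDE x joint NIE` holds exactly.
#'
#' @param expanded result of [expand_and_impute()].
#' @return Object of class `natural_effects_fit`: `theta` (all
#'   coefficients), the five odds ratios, proportions mediated `pm_m1`,
#'   `pm_m2`, `pm_joint`, and `log_or`.
#' @export
fit_natural_model <- function(expanded) {
  cf <- attr(expanded, "confounders")
  Xd <- cbind(`(Intercept)` = 1, x0 = expanded$x0, x1 = expanded$x1,
              x2 = expanded$x2, as.matrix(expanded[cf]))
  fit <- fit_logit(Xd, expanded$eh, expanded$w)
  if (!fit$converged) stop("natural model did not converge")
  theta <- fit$coefficients
  names(theta) <- colnames(Xd)
  new_natural_effects_fit(theta)
}

new_natural_effects_fit <- function(theta, B = NULL, seed = NULL, m = NULL,
                                    ci = NULL, level = NULL) {
  log_or <- c(nde = theta[["x0"]], nie_m1 = theta[["x1"]], nie_m2 = theta[["x2"]],
              nie_joint = theta[["x1"]] + theta[["x2"]],
              te = theta[["x0"]] + theta[["x1"]] + theta[["x2"]])
  or_ <- exp(log_or)
  structure(list(
    theta = theta,
    or_nde = or_[["nde"]], or_nie_m1 = or_[["nie_m1"]],
    or_nie_m2 = or_[["nie_m2"]], or_nie_joint = or_[["nie_joint"]],
    or_te = or_[["te"]], log_or = log_or,
    pm_m1 = proportion_mediated(or_[["nde"]], or_[["nie_m1"]]),
    pm_m2 = proportion_mediated(or_[["nde"]], or_[["nie_m2"]]),
    pm_joint = proportion_mediated(or_[["nde"]], or_[["nie_joint"]]),
    ci = ci, level = level, B = B, seed = seed, m = m),
    class = "natural_effects_fit")
}

#' @export
print.natural_effects_fit <- function(x, ...) {
  cat("Natural effects decomposition (odds-ratio scale)\n")
  lab <- c(te = "Total Effect", nde = "Natural Direct Effect",
           nie_m1 = "NIE via M1", nie_m2 = "NIE via M2",
           nie_joint = "Joint NIE via M1 and M2")
  pm <- c(te = NA, nde = NA, nie_m1 = x$pm_m1, nie_m2 = x$pm_m2,
          nie_joint = x$pm_joint)
  for (e in names(lab)) {
    ci_txt <- if (!is.null(x$ci) && e %in% rownames(x$ci)) {
      sprintf(" (%.2f to %.2f)", round_half_up(x$ci[e, 1]), round_half_up(x$ci[e, 2]))
    } else ""
    pm_txt <- if (!is.na(pm[e])) sprintf("  PM %.2f%%", 100 * pm[[e]]) else ""
    cat(sprintf("  %-24s %5.2f%s%s\n", lab[[e]], round_half_up(exp(x$log_or[[e]])),
                ci_txt, pm_txt))
  }
  if (!is.null(x$m)) cat(sprintf("  pooled over %d imputations\n", x$m))
  if (!is.null(x$B)) cat(sprintf("  percentile bootstrap, B = %d\n", x$B))
  invisible(x)
}

#' Proportion mediated on the odds-ratio scale
#'
#' `PM = OR_NDE (OR_NIE - 1) / (OR_NDE x OR_NIE - 1)`.  Identities:
#' `PM(x, 1) = 0` for any `x != 1`, and `PM(1, x) = 1` for any `x > 1`.
#' Reported as a percentage in display output.
#'
#' @param or_nde,or_nie natural direct / indirect effect odds ratios,
#'   with `or_nde * or_nie != 1`.
#' @return The proportion mediated; `NA` with attribute `undefined = TRUE`
#'   when the denominator is within machine epsilon of zero.
#' @export
#' @examples
#' proportion_mediated(2.02, 1.06)  # 0.1062
proportion_mediated <- function(or_nde, or_nie) {
  den <- or_nde * or_nie - 1
  if (abs(den) < .Machine$double.eps * 4) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  or_nde * (or_nie - 1) / den
}

#' Point estimation of the natural effects on one complete analysis set
#'
#' Convenience wrapper running [fit_outcome_imputation_model()],
#' [fit_mediator_model()], [expand_and_impute()] and [fit_natural_model()].
#'
#' @inheritParams fit_outcome_imputation_model
#' @return A `natural_effects_fit` (point estimates, no CIs).
#' @export
natural_effects <- function(analysis_set, spec = natural_model_spec()) {
  om <- fit_outcome_imputation_model(analysis_set, spec)
  mm <- fit_mediator_model(analysis_set, spec)
  fit_natural_model(expand_and_impute(analysis_set, om, mm))
}

#' Non-parametric bootstrap confidence intervals
#'
#' Resamples children (rows) with replacement, reruns the supplied
#' estimator on each replicate, and returns percentile intervals for all
#' five effect odds ratios.  Replicate failures are logged and skipped; the
#' call errors if more than 5% fail.  With a fixed `spec$seed` the
#' replicate stream -- and hence the intervals -- is reproducible.
#'
#' @param analysis_set the data resampled at child level.
#' @param spec a [natural_model_spec()] (supplies `B`, `seed`, `level`).
#' @param estimator function of one data.frame returning a named numeric
#'   vector of log odds ratios (`nde`, `nie_m1`, `nie_m2`, `nie_joint`,
#'   `te`); default: the [natural_effects()] point estimator.
#' @return List: `ci` (matrix, OR scale, one row per effect), `replicates`
#'   (B x 5 log-OR matrix), `n_failed`.
#' @export
bootstrap_cis <- function(analysis_set, spec = natural_model_spec(),
                          estimator = NULL) {
  if (is.null(estimator)) estimator <- function(d) natural_effects(d, spec)$log_or
  n <- nrow(analysis_set)
  seeds <- derive_seeds(spec$seed, spec$B)
  reps <- matrix(NA_real_, spec$B, 5,
                 dimnames = list(NULL, c("nde", "nie_m1", "nie_m2", "nie_joint", "te")))
  n_failed <- 0
  for (b in seq_len(spec$B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    # replicate-level separation fallbacks are routine in small resamples;
    # they are silenced here, failures are counted instead
    est <- tryCatch(suppressWarnings(estimator(analysis_set[idx, , drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1 else reps[b, ] <- est[colnames(reps)]
  }
  if (n_failed > 0.05 * spec$B) {
    stop(sprintf("bootstrap failed in %d/%d replicates", n_failed, spec$B))
  }
  a <- (1 - spec$level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(ci) <- c("low", "high")
  list(ci = exp(ci), replicates = reps, n_failed = n_failed)
}

#' Pool natural-effects fits over imputations
#'
#' Rubin's rule for point estimates: the pooled coefficient vector is the
#' arithmetic mean of the per-imputation `theta` on the log-odds scale;
#' odds ratios and proportions mediated are recomputed from the pooled
#' coefficients (so the exact decomposition identity is preserved).
#'
#' @param fits list of `natural_effects_fit` objects with identical
#'   coefficient layouts.
#' @return A pooled `natural_effects_fit` with `m = length(fits)`.
#' @export
pool_over_imputations <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "natural_effects_fit")))
  nm <- names(fits[[1]]$theta)
  for (f in fits) {
    if (!identical(names(f$theta), nm)) stop("mismatched natural-model specifications")
  }
  theta <- Reduce(`+`, lapply(fits, `[[`, "theta")) / length(fits)
  new_natural_effects_fit(theta, m = length(fits))
}

#' Natural effects with multiple imputation and bootstrap
#'
#' Full inferential procedure for an analysis set with missing flags:
#' point estimates are Rubin-pooled over `m` chained-equation imputations;
#' confidence intervals come from a boot-then-impute scheme in which each
#' of the `B` bootstrap replicates resamples children, performs one
#' stochastic imputation and re-estimates, so the intervals carry both
#' sampling and imputation uncertainty.
#'
#' @param analysis_set an `analysis_set` (missing flags allowed).
#' @param spec a [natural_model_spec()].
#' @param m number of imputations for the point estimate.
#' @param n_iterations chained-equation cycles per imputation.
#' @return A `natural_effects_fit` with percentile `ci` attached.
#' @export
natural_effects_mi <- function(analysis_set, spec = natural_model_spec(),
                               m = 20, n_iterations = 50) {
  cf <- spec_confounders(analysis_set, spec)
  cols <- c("X", "M1", "M2", "Y", cf)
  seeds <- derive_seeds(spec$seed, 2)
  impute_once <- function(d, m_, seed_) {
    imp <- chained_impute(d[cols], m = m_, n_iterations = n_iterations,
                          seed = seed_)
    lapply(imp$imputations, function(tab) {
      out <- cbind(tab, w = d$w)
      attr(out, "confounders") <- cf
      out
    })
  }
  if (anyNA(analysis_set[cols])) {
    completed <- impute_once(analysis_set, m, seeds[1])
  } else {
    completed <- list(`attr<-`(cbind(analysis_set[cols], w = analysis_set$w),
                               "confounders", cf))
  }
  fits <- lapply(completed, natural_effects, spec = spec)
  pooled <- pool_over_imputations(fits)

  boot_estimator <- function(d) {
    one <- if (anyNA(d[cols])) impute_once(d, 1, sample.int(2^30, 1))[[1]] else d
    natural_effects(one, spec)$log_or
  }
  bs <- bootstrap_cis(analysis_set, spec, estimator = boot_estimator)
  pooled$ci <- bs$ci
  pooled$level <- spec$level
  pooled$B <- spec$B
  pooled$seed <- spec$seed
  pooled
}
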