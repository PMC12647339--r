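#' Simulate a family-stress cohort
#'
#' Draws `n_children` records from the structural model `C -> X -> M1 -> M2
#' -> Y` and back-generates raw survey fields (household income and
#' composition, six DASS items, CPRS-SF closeness/conflict sums, SDQ total,
#' confounder bands, survey weight) so that applying the preprocessing
#' cut-offs recorded in `attr(cohort, "cutpoints")` recovers the latent
#' binary flags exactly.  Raw scores are drawn uniformly from the side of
#' the relevant cut-off dictated by each latent flag (the non-abnormal SDQ
#' band is split between normal and borderline scores).
#'
#' Because exposure and mediator flags are defined against fixed population
#' cut-offs (as when quintiles are formed on a full cohort and analysed on a
#' subsample), the realised flag prevalence is the calibrated population
#' value (e.g. 38.9% exposed), not exactly 40%.
#'
#' @param params a [structural_params()] object.
#' @param inject_missing logical; apply [inject_missingness()] as the final
#'   step (default `TRUE`).  Use `FALSE` to obtain the complete cohort for
#'   round-trip checks.
#' @return A `data.frame` of class `fsm_cohort` with attributes
#'   `cutpoints` (named list: `income`, `dass`, `closeness`, `conflict`,
#'   fixed `sdq` cut 17), `latents` (data.frame of the true `X`, `M1`, `M2`,
#'   `Y`) and `params`.
#' @export
#' @examples
#' cohort <- generate_cohort(structural_params(n_children = 200, seed = 7))
#' str(attr(cohort, "cutpoints"))
generate_cohort <- function(params, inject_missing = TRUE) {
  stopifnot(inherits(params, "structural_params"))
  set.seed(params$seed)
  n <- params$n_children
  prev <- params$conf_prevalences
  C <- sapply(prev, function(p) stats::rbinom(n, 1L, p))
  C <- matrix(C, nrow = n, dimnames = list(NULL, names(prev)))

  X  <- stats::rbinom(n, 1L, stats::plogis(struct_lp(params$alpha_X, C)))
  M1 <- stats::rbinom(n, 1L, stats::plogis(struct_lp(params$alpha_M1, C, X = X)))
  M2 <- stats::rbinom(n, 1L, stats::plogis(struct_lp(params$alpha_M2, C, X = X, M1 = M1)))
  Y  <- stats::rbinom(n, 1L, stats::plogis(struct_lp(params$alpha_Y, C, X = X, M1 = M1, M2 = M2)))

  rp <- params$raw_scale_params

  # confounder bands consistent with the binary flags
  educ <- ifelse(C[, "low_educ"] == 1,
                 ifelse(stats::runif(n) < 0.152 / 0.215, "standard_grade", "no_qualifications"),
                 ifelse(stats::runif(n) < 0.700 / 0.785, "degree_or_vocational", "higher"))
  agep <- c(`20-29` = 0.361, `30-39` = 0.557, `40+` = 0.037)
  age <- ifelse(C[, "low_mat_age"] == 1, "<20",
                sample(names(agep), n, replace = TRUE, prob = agep))
  nchild <- ifelse(C[, "children_4plus"] == 1, "4+",
                   ifelse(stats::runif(n) < 0.419 / 0.961, "1", "2-3"))

  # household composition and income (equivalised income back-generated
  # around the population 40th percentile, then de-equivalised)
  n_adults <- ifelse(C[, "one_parent"] == 1, 1L, 2L)
  n_other <- stats::rbinom(n, 1L, 0.05)
  n_u14 <- ifelse(nchild == "1", 1L,
                  ifelse(nchild == "2-3", sample(2:3, n, replace = TRUE),
                         sample(4:6, n, replace = TRUE)))
  tau <- stats::qlnorm(0.4, rp$income_meanlog, rp$income_sdlog)
  u <- ifelse(X == 1, stats::runif(n, 0, 0.4), stats::runif(n, 0.4, 1))
  eq_income <- stats::qlnorm(u, rp$income_meanlog, rp$income_sdlog)
  factor_oecd <- 1 + 0.5 * (n_adults - 1L + n_other) + 0.3 * n_u14
  hh_income <- eq_income * factor_oecd

  # DASS: sum on the flagged side of the cut, decomposed into six 0-3 items
  # by sampling `sum` of the 18 unit slots without replacement
  dsum <- ifelse(M1 == 1,
                 sample_int_range(rp$dass_cut, 18L, n),
                 sample_int_range(0L, rp$dass_cut - 1L, n))
  dass <- t(vapply(dsum, function(s) {
    slots <- sample.int(18L, s)
    tabulate((slots - 1L) %/% 3L + 1L, nbins = 6L)
  }, integer(6)))
  colnames(dass) <- paste0("dass_", 1:6)

  # CPRS-SF: closeness 7-35, conflict 8-40; M2 = low closeness OR high conflict
  clo_lo <- function(k) sample_int_range(7L, rp$closeness_cut, k)
  clo_hi <- function(k) sample_int_range(rp$closeness_cut + 1L, 35L, k)
  con_lo <- function(k) sample_int_range(8L, rp$conflict_cut - 1L, k)
  con_hi <- function(k) sample_int_range(rp$conflict_cut, 40L, k)
  closeness <- integer(n); conflict <- integer(n)
  idx0 <- which(M2 == 0)
  closeness[idx0] <- clo_hi(length(idx0)); conflict[idx0] <- con_lo(length(idx0))
  idx1 <- which(M2 == 1)
  kind <- sample(c("lo", "hi", "both"), length(idx1), replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  i_lo <- idx1[kind == "lo"]; i_hi <- idx1[kind == "hi"]; i_bo <- idx1[kind == "both"]
  closeness[i_lo] <- clo_lo(length(i_lo)); conflict[i_lo] <- con_lo(length(i_lo))
  closeness[i_hi] <- clo_hi(length(i_hi)); conflict[i_hi] <- con_hi(length(i_hi))
  closeness[i_bo] <- clo_lo(length(i_bo)); conflict[i_bo] <- con_hi(length(i_bo))

  # SDQ total: abnormal >= 17; non-abnormal split normal/borderline
  sdq <- integer(n)
  iY <- which(Y == 1)
  sdq[iY] <- sample_int_range(17L, 40L, length(iY))
  i0 <- which(Y == 0)
  bl <- stats::runif(length(i0)) < rp$borderline_frac
  sdq[i0[bl]] <- sample_int_range(14L, 16L, sum(bl))
  sdq[i0[!bl]] <- sample_int_range(0L, 13L, sum(!bl))

  weight <- if (params$weight_model == "lognormal") {
    w <- stats::rlnorm(n, 0, 0.3); w / mean(w)
  } else rep(1, n)

  cohort <- data.frame(
    child_id = seq_len(n),
    hh_income = hh_income, n_adults = n_adults,
    n_other_14plus = n_other, n_children_u14 = n_u14,
    dass, closeness = closeness, conflict = conflict, sdq_total = sdq,
    maternal_education = factor(educ, levels = c("degree_or_vocational",
      "higher", "standard_grade", "no_qualifications")),
    maternal_age_band = factor(age, levels = c("<20", "20-29", "30-39", "40+")),
    unemployed = C[, "unemployed"],
    n_children_band = factor(nchild, levels = c("1", "2-3", "4+")),
    one_parent = C[, "one_parent"],
    ethnic_minority = C[, "ethnic_minority"],
    weight = weight)
  attr(cohort, "cutpoints") <- list(
    income = tau, dass = rp$dass_cut, closeness = rp$closeness_cut,
    conflict = rp$conflict_cut, sdq = 17L)
  attr(cohort, "latents") <- data.frame(X = X, M1 = M1, M2 = M2, Y = Y)
  attr(cohort, "params") <- params
  class(cohort) <- c("fsm_cohort", "data.frame")
  if (inject_missing && any(params$missing_rates > 0)) {
    cohort <- inject_missingness(cohort, params,
                                 seed = derive_seeds(params$seed, 1))
  }
  cohort
}

# uniform integer draw on [lo, hi], vectorised; errors if the range is empty
sample_int_range <- function(lo, hi, k) {
  if (k == 0) return(integer(0))
  if (hi < lo) stop("impossible raw-score back-generation: empty score range",
                    call. = FALSE)
  lo + floor(stats::runif(k) * (hi - lo + 1L))
}

#' Inject missingness into a cohort
#'
#' Sets cohort cells to `NA` according to the mechanism in `params`.
#' `"MCAR"` uses i.i.d. Bernoulli draws at each variable's rate.  `"MAR"`
#' makes missingness of the score variables (`hh_income`, `dass`,
#' `closeness`, `conflict`, `sdq_total`) depend on the one-parent and
#' unemployment confounders through a logistic link with slope
#' `missing_coef`; confounder fields remain MCAR.  `"MNAR"` makes score
#' missingness depend on the (standardised) value of the score itself.
#' Rates named `dass` remove all six DASS items jointly, emulating
#' whole-scale non-response.
#'
#' @param cohort an `fsm_cohort` (or any data.frame with the same columns).
#' @param params a [structural_params()] object supplying `missing_rates`,
#'   `missing_mechanism` and `missing_coef`.
#' @param seed integer seed for the missingness draws.
#' @return The cohort with `NA` cells; attributes are preserved.
#' @export
inject_missingness <- function(cohort, params, seed = params$seed) {
  stopifnot(inherits(params, "structural_params"))
  rates <- params$missing_rates
  if (all(rates == 0)) return(cohort)
  mech <- params$missing_mechanism
  if (!mech %in% c("MCAR", "MAR", "MNAR")) stop("unknown missingness mechanism")
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  score_vars <- c("hh_income", "dass", "closeness", "conflict", "sdq_total")
  lat <- attr(cohort, "latents")

  mar_driver <- with(cohort, one_parent + unemployed)
  for (v in names(rates)) {
    r <- rates[[v]]
    if (r <= 0) next
    target_cols <- if (v == "dass") paste0("dass_", 1:6) else v
    if (!all(target_cols %in% names(cohort))) next
    if (mech == "MCAR" || !(v %in% score_vars)) {
      p <- rep(r, n)
    } else if (mech == "MAR") {
      z <- mar_driver
      off <- stats::uniroot(function(b) mean(stats::plogis(b + params$missing_coef * z)) - r,
                            c(-20, 20))$root
      p <- stats::plogis(off + params$missing_coef * z)
    } else { # MNAR on the (complete) value itself
      val <- if (v == "dass") rowSums(cohort[paste0("dass_", 1:6)]) else cohort[[v]]
      val <- as.numeric(val)
      z <- (val - mean(val, na.rm = TRUE)) / (stats::sd(val, na.rm = TRUE) + 1e-12)
      off <- stats::uniroot(function(b) mean(stats::plogis(b + params$missing_coef * z)) - r,
                            c(-20, 20))$root
      p <- stats::plogis(off + params$missing_coef * z)
    }
    hit <- stats::runif(n) < p
    for (col in target_cols) cohort[[col]][hit] <- NA
  }
  attr(cohort, "latents") <- lat
  cohort
}

#' Ground-truth natural effects by counterfactual Monte Carlo
#'
#' Computes population (marginal, confounder-averaged) odds ratios for the
#' natural-effects decomposition implied by a [structural_params()] object,
#' by simulating the nested counterfactuals `M1(x1)`, `M2(x2, M1(x2))`,
#' `Y(x0, m1, m2)` at the index settings `(0,0,0)`, `(1,0,0)`, `(1,1,0)`,
#' `(1,1,1)`.  The confounder vector is drawn `n_mc` times; within each draw
#' the counterfactual outcome probability of every setting is evaluated in
#' closed form (Rao-Blackwellised Monte Carlo), with the copy of `M1`
#' entering the outcome (index `x1`) integrated independently of the copy
#' driving `M2` (index `x2`), matching the estimand of the
#' expansion-imputation estimator.
#'
#' Effects are odds ratios between successive counterfactual probabilities:
#' NDE = odds(1,0,0)/odds(0,0,0); NIE via M1 = odds(1,1,0)/odds(1,0,0);
#' NIE via M2 = odds(1,1,1)/odds(1,1,0); joint NIE = product of the two;
#' TE = odds(1,1,1)/odds(0,0,0), so TE = NDE x joint NIE by construction.
#'
#' @param params a [structural_params()] object.
#' @param n_mc number of Monte-Carlo confounder draws (>= 1e5 recommended).
#' @param seed integer seed.
#' @return Object of class `true_effects`: the five odds ratios, their
#'   log-scale Monte-Carlo standard errors (`mc_se`), the four
#'   counterfactual probabilities (`p_cf`), `n_mc`, and `unbounded` flag
#'   set when a counterfactual probability is degenerate (0 or 1).
#' @export
oracle_effects <- function(params, n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(params, "structural_params"))
  set.seed(as.integer(seed))
  prev <- params$conf_prevalences
  C <- sapply(prev, function(p) stats::rbinom(n_mc, 1L, p))
  C <- matrix(C, nrow = n_mc, dimnames = list(NULL, names(prev)))

  pM1 <- function(x) stats::plogis(struct_lp(params$alpha_M1, C, X = rep(x, n_mc)))
  pM2 <- function(x, m1) stats::plogis(struct_lp(params$alpha_M2, C,
    X = rep(x, n_mc), M1 = rep(m1, n_mc)))
  pY <- function(x, m1, m2) stats::plogis(struct_lp(params$alpha_Y, C,
    X = rep(x, n_mc), M1 = rep(m1, n_mc), M2 = rep(m2, n_mc)))

  cf_prob <- function(x0, x1, x2) {
    pm1_y <- pM1(x1)
    pm1_m <- pM1(x2)
    pm2 <- (1 - pm1_m) * pM2(x2, 0) + pm1_m * pM2(x2, 1)
    (1 - pm1_y) * (1 - pm2) * pY(x0, 0, 0) +
      (1 - pm1_y) * pm2 * pY(x0, 0, 1) +
      pm1_y * (1 - pm2) * pY(x0, 1, 0) +
      pm1_y * pm2 * pY(x0, 1, 1)
  }
  settings <- list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  P <- sapply(settings, function(s) cf_prob(s[1], s[2], s[3]))
  p_hat <- colMeans(P)
  names(p_hat) <- c("p000", "p100", "p110", "p111")

  unbounded <- any(p_hat <= 0 | p_hat >= 1)
  odds <- p_hat / (1 - p_hat)
  lo <- log(odds)
  log_or <- c(nde = lo[[2]] - lo[[1]], nie_m1 = lo[[3]] - lo[[2]],
              nie_m2 = lo[[4]] - lo[[3]],
              nie_joint = lo[[4]] - lo[[2]], te = lo[[4]] - lo[[1]])

  # delta method on the log-odds of the four MC-estimated probabilities
  Sig <- stats::cov(P) / n_mc
  g <- 1 / (p_hat * (1 - p_hat))
  contrasts <- list(nde = c(-1, 1, 0, 0), nie_m1 = c(0, -1, 1, 0),
                    nie_m2 = c(0, 0, -1, 1), nie_joint = c(0, -1, 0, 1),
                    te = c(-1, 0, 0, 1))
  mc_se <- vapply(contrasts, function(a) {
    v <- a * g
    sqrt(drop(t(v) %*% Sig %*% v))
  }, numeric(1))

  structure(list(
    or_te = exp(log_or[["te"]]), or_nde = exp(log_or[["nde"]]),
    or_nie_m1 = exp(log_or[["nie_m1"]]), or_nie_m2 = exp(log_or[["nie_m2"]]),
    or_nie_joint = exp(log_or[["nie_joint"]]),
    log_or = log_or, mc_se = mc_se, p_cf = p_hat,
    n_mc = n_mc, unbounded = unbounded), class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat("Monte-Carlo ground-truth natural effects (marginal odds ratios)\n")
  eff <- c(TE = x$or_te, NDE = x$or_nde, `NIE(M1)` = x$or_nie_m1,
           `NIE(M2)` = x$or_nie_m2, `NIE(joint)` = x$or_nie_joint)
  se <- x$mc_se[c("te", "nde", "nie_m1", "nie_m2", "nie_joint")]
  for (i in seq_along(eff)) {
    cat(sprintf("  %-10s %6.3f  (MC se of log OR %.2e)\n", names(eff)[i], eff[i], se[i]))
  }
  if (x$unbounded) cat("  WARNING: degenerate counterfactual probability; ORs unbounded\n")
  invisible(x)
}
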