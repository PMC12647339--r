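#' Structural parameters of the family-stress cohort simulator
#'
#' Defines the data-generating process used by [generate_cohort()] and
#' [oracle_effects()]: six independent binary baseline confounders `C`, a
#' binary exposure `X` (low equivalised household income), two causally
#' ordered binary mediators `M1` (reduced maternal wellbeing) and `M2` (poor
#' child--parent relationship quality), and a binary outcome `Y` (SDQ total
#' difficulties in the abnormal band), each drawn from a logistic structural
#' equation in causal order `C -> X -> M1 -> M2 -> Y`.
#'
#' The default coefficients are calibrated so that, at the population level,
#' the exposure prevalence is 38.9% and the stratum-specific prevalences are
#' M1: 30.6%/18.4%, M2: 40.6%/31.5% and Y: 8.3%/2.7% (exposed/unexposed) --
#' the marginals of a large Scottish birth-cohort analysis sample.
#' Calibration solves the intercepts and exposure coefficients exactly by
#' enumerating the 64 confounder patterns; the confounder slopes are fixed
#' design choices (slopes on `X` anchored to published unadjusted odds
#' ratios, slopes on `M1`/`M2`/`Y` modest adjusted associations).
#'
#' @param n_children number of children (rows) to simulate.
#' @param seed integer seed; a fixed seed gives bit-identical cohorts.
#' @param conf_prevalences named probabilities of the six binary confounders.
#' @param alpha_X,alpha_M1,alpha_M2,alpha_Y named numeric vectors of
#'   log-odds-scale coefficients.  `alpha_X` holds `intercept` plus one
#'   coefficient per confounder; `alpha_M1` adds `X`; `alpha_M2` adds `X` and
#'   `M1`; `alpha_Y` adds `X`, `M1`, `M2` and optionally `X:M1`, `X:M2`.
#' @param raw_scale_params list controlling raw-score back-generation:
#'   `income_meanlog`, `income_sdlog` (equivalised income is log-normal),
#'   `dass_cut` (six-item sum at or above this is the top quintile),
#'   `closeness_cut` (at or below = lowest quintile), `conflict_cut`
#'   (at or above = highest quintile), `borderline_frac` (share of the
#'   non-abnormal SDQ band generated in 14--16).
#' @param missing_rates named per-variable missingness probabilities in
#'   `[0, 1)`; names must be cohort column names (use `dass` for the six
#'   DASS items jointly).
#' @param missing_mechanism one of `"MCAR"`, `"MAR"` (missingness of scores
#'   depends on confounders) or `"MNAR"` (depends on the value itself).
#' @param missing_coef log-odds shift used by the MAR/MNAR mechanisms.
#' @param weight_model `"unit"` (all weights 1) or `"lognormal"`
#'   (mean-one log-normal survey weights, sdlog 0.3).
#'
#' @return An object of class `structural_params`.
#' @seealso [generate_cohort()], [inject_missingness()], [oracle_effects()]
#' @export
#' @examples
#' p <- structural_params(n_children = 500, seed = 1)
#' cohort <- generate_cohort(p)
structural_params <- function(n_children = 3639,
                              seed = 2026L,
                              conf_prevalences = c(
                                low_educ = 0.215, low_mat_age = 0.044,
                                unemployed = 0.344, children_4plus = 0.039,
                                one_parent = 0.141, ethnic_minority = 0.027),
                              alpha_X = c(
                                intercept = -1.806684,
                                low_educ = log(4.40), low_mat_age = log(8.13),
                                unemployed = log(3.86), children_4plus = log(3.78),
                                one_parent = log(10.53), ethnic_minority = log(2.96)),
                              alpha_M1 = c(
                                intercept = -1.711116, X = 0.322862,
                                low_educ = log(1.5), low_mat_age = log(1.3),
                                unemployed = log(1.5), children_4plus = log(1.3),
                                one_parent = log(1.8), ethnic_minority = log(1.2)),
                              alpha_M2 = c(
                                intercept = -1.041213, X = 0.103916, M1 = log(2.0),
                                low_educ = log(1.4), low_mat_age = log(1.2),
                                unemployed = log(1.2), children_4plus = log(1.2),
                                one_parent = log(1.4), ethnic_minority = log(1.2)),
                              alpha_Y = c(
                                intercept = -4.187351, X = 0.758684,
                                M1 = log(1.8), M2 = log(2.0),
                                low_educ = log(1.5), low_mat_age = log(1.3),
                                unemployed = log(1.3), children_4plus = log(1.2),
                                one_parent = log(1.5), ethnic_minority = log(1.2)),
                              raw_scale_params = list(
                                income_meanlog = log(22000), income_sdlog = 0.6,
                                dass_cut = 12L, closeness_cut = 24L,
                                conflict_cut = 24L, borderline_frac = 0.0514),
                              missing_rates = c(
                                hh_income = 0.080, sdq_total = 0.079,
                                dass = 0.050, closeness = 0.050, conflict = 0.050,
                                maternal_education = 0.017, maternal_age_band = 0.018,
                                unemployed = 0.014, n_children_band = 0.013,
                                one_parent = 0.023, ethnic_minority = 0.014),
                              missing_mechanism = c("MCAR", "MAR", "MNAR"),
                              missing_coef = 1.0,
                              weight_model = c("unit", "lognormal")) {
  missing_mechanism <- match.arg(missing_mechanism)
  weight_model <- match.arg(weight_model)
  stopifnot(n_children >= 1, is.finite(seed))
  if (any(conf_prevalences < 0 | conf_prevalences > 1)) {
    stop("confounder prevalences must lie in [0, 1]")
  }
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missing rates must lie in [0, 1)")
  }
  for (a in list(alpha_X, alpha_M1, alpha_M2, alpha_Y)) {
    if (any(!is.finite(a))) stop("structural coefficients must be finite")
  }
  cn <- names(conf_prevalences)
  stopifnot(all(cn %in% names(alpha_X)), all(cn %in% names(alpha_M1)),
            all(cn %in% names(alpha_M2)), all(cn %in% names(alpha_Y)),
            "X" %in% names(alpha_M1), all(c("X", "M1") %in% names(alpha_M2)),
            all(c("X", "M1", "M2") %in% names(alpha_Y)))
  structure(list(
    n_children = as.integer(n_children), seed = as.integer(seed),
    conf_prevalences = conf_prevalences,
    alpha_X = alpha_X, alpha_M1 = alpha_M1, alpha_M2 = alpha_M2,
    alpha_Y = alpha_Y, raw_scale_params = raw_scale_params,
    missing_rates = missing_rates, missing_mechanism = missing_mechanism,
    missing_coef = missing_coef, weight_model = weight_model),
    class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Family-stress structural parameters\n")
  cat(sprintf("  n_children: %d   seed: %d\n", x$n_children, x$seed))
  cat(sprintf("  confounders: %s\n", paste(names(x$conf_prevalences), collapse = ", ")))
  cat(sprintf("  missingness: %s, mechanism %s\n",
              paste0(round(range(x$missing_rates), 3), collapse = "-"),
              x$missing_mechanism))
  invisible(x)
}

# linear predictors of the four structural equations, vectorised over rows
struct_lp <- function(alpha, C, X = NULL, M1 = NULL, M2 = NULL) {
  cn <- colnames(C)
  lp <- alpha[["intercept"]] + drop(C %*% alpha[cn])
  if (!is.null(X) && "X" %in% names(alpha)) lp <- lp + alpha[["X"]] * X
  if (!is.null(M1) && "M1" %in% names(alpha)) lp <- lp + alpha[["M1"]] * M1
  if (!is.null(M2) && "M2" %in% names(alpha)) lp <- lp + alpha[["M2"]] * M2
  if (!is.null(X) && !is.null(M1) && "X:M1" %in% names(alpha)) lp <- lp + alpha[["X:M1"]] * X * M1
  if (!is.null(X) && !is.null(M2) && "X:M2" %in% names(alpha)) lp <- lp + alpha[["X:M2"]] * X * M2
  lp
}
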