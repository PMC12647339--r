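#' OECD-modified income equivalisation
#'
#' Divides household income by the OECD-modified equivalence factor:
#' 1.0 for the first adult, 0.5 for each additional person aged 14 or over,
#' 0.3 for each child under 14.
#'
#' @param income non-negative household income (vectorised).
#' @param n_adults number of adults (>= 1).
#' @param n_other_14plus additional household members aged 14+ (excluding
#'   the adults counted in `n_adults`).
#' @param n_children_u14 children under 14.
#' @return Equivalised income, same length as `income`.
#' @export
#' @examples
#' oecd_equivalise(21000, n_adults = 2, n_children_u14 = 2)  # 10000
oecd_equivalise <- function(income, n_adults, n_other_14plus = 0,
                            n_children_u14 = 0) {
  if (any(income < 0, na.rm = TRUE)) stop("income must be non-negative")
  if (any(n_adults + n_other_14plus + n_children_u14 < 1, na.rm = TRUE) ||
      any(n_adults < 1, na.rm = TRUE)) {
    stop("empty household: at least one adult is required")
  }
  income / (1.0 + 0.5 * (n_adults - 1 + n_other_14plus) + 0.3 * n_children_u14)
}

#' Weighted quintile flags
#'
#' Flags observations relative to a weighted empirical quantile of `values`.
#' `"bottom_two"` flags values at or below the 0.40 quantile (the lowest two
#' quintile groups), `"bottom_one"` at or below the 0.20 quantile,
#' `"top_one"` at or above the upper 0.20 cut (computed on the negated
#' values, so ties at the cut are flagged).  The quantile is the smallest
#' observed value whose weighted ECDF reaches the target mass, so tied
#' values at the cut always enter the flagged group.  Missing values give
#' missing flags.  Supplying `cutpoint` bypasses quantile estimation and
#' flags against the fixed threshold instead (at-or-below for the bottom
#' rules, at-or-above for `"top_one"`) -- used when cut-offs were formed on
#' a larger reference sample.
#'
#' @param values numeric vector (>= 5 non-missing unless `cutpoint` given).
#' @param rule `"bottom_two"`, `"top_one"` or `"bottom_one"`.
#' @param weights optional positive weights (default: unweighted).
#' @param cutpoint optional fixed threshold.
#' @return Integer 0/1 vector with attribute `cutpoint` (the threshold used;
#'   flagged side as described above).  If all non-missing values are equal
#'   no quintile exists: every flag is 0 and a warning is raised.
#' @export
#' @examples
#' quintile_flag(1:10, "bottom_two")  # flags 1-4
quintile_flag <- function(values, rule = c("bottom_two", "top_one", "bottom_one"),
                          weights = NULL, cutpoint = NULL) {
  rule <- match.arg(rule)
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  if (is.null(cutpoint)) {
    if (sum(ok) < 5) stop("need at least 5 non-missing values to form quintiles")
    if (length(unique(values[ok])) == 1) {
      warning("all values identical: no quintile exists, returning all-unflagged")
      out[ok] <- 0L
      attr(out, "cutpoint") <- NA_real_
      return(out)
    }
    cutpoint <- switch(rule,
      bottom_two = weighted_quantile_cut(values, 0.4, weights),
      bottom_one = weighted_quantile_cut(values, 0.2, weights),
      top_one = -weighted_quantile_cut(-values, 0.2, weights))
  }
  out[ok] <- if (rule == "top_one") {
    as.integer(values[ok] >= cutpoint)
  } else {
    as.integer(values[ok] <= cutpoint)
  }
  attr(out, "cutpoint") <- cutpoint
  out
}

#' SDQ total-difficulties banding
#'
#' Bands a Strengths and Difficulties Questionnaire total score (0--40)
#' into `normal` (< 14), `borderline` (14--16) or `abnormal` (>= 17).
#' The binary mental-health-difficulties outcome is `band == "abnormal"`.
#'
#' @param total integer SDQ total difficulties score(s), 0--40.
#' @return Factor with levels `normal`, `borderline`, `abnormal`;
#'   attribute `flag` holds the 0/1 abnormal indicator.
#' @export
#' @examples
#' sdq_band(c(13, 14, 16, 17))
sdq_band <- function(total) {
  bad <- !is.na(total) & (total < 0 | total > 40 | total != floor(total))
  if (any(bad)) stop("SDQ total out of range [0, 40]")
  band <- cut(total, breaks = c(-1, 13, 16, 40),
              labels = c("normal", "borderline", "abnormal"))
  attr(band, "flag") <- ifelse(is.na(band), NA_integer_,
                               as.integer(band == "abnormal"))
  band
}

#' Reduced maternal wellbeing flag from six DASS items
#'
#' Sums the six DASS items (each scored 0--3) and flags mothers in the top
#' quintile of the summed score within the analysis sample (or at/above a
#' fixed reference `cutpoint`).  Any missing item makes the flag missing --
#' partial sums are not imputed here.
#'
#' @param dass_items matrix or data.frame with six columns of item scores.
#' @param weights,cutpoint passed to [quintile_flag()] (`"top_one"` rule).
#' @return Integer 0/1/NA vector with attribute `cutpoint`.
#' @export
dass_flag <- function(dass_items, weights = NULL, cutpoint = NULL) {
  dass_items <- as.matrix(dass_items)
  if (ncol(dass_items) != 6) stop("exactly six DASS items are required")
  if (any(dass_items < 0 | dass_items > 3, na.rm = TRUE)) {
    stop("DASS items must be scored 0-3")
  }
  sums <- ifelse(rowSums(is.na(dass_items)) > 0, NA_real_, rowSums(dass_items))
  quintile_flag(sums, "top_one", weights = weights, cutpoint = cutpoint)
}

#' Poor child--parent relationship quality flag (CPRS-SF)
#'
#' Flags dyads whose closeness subscale sum falls in the lowest quintile
#' *or* whose conflict subscale sum falls in the highest quintile.  With one
#' subscale missing the flag is 1 if the observed subscale already
#' qualifies, and missing otherwise; with both missing it is missing.
#'
#' @param closeness,conflict subscale sums (closeness: 7 items, conflict: 8).
#' @param weights optional weights for the quintile cuts.
#' @param cutpoints optional list with fixed `closeness` and `conflict`
#'   thresholds (flag closeness <= cut, conflict >= cut).
#' @return Integer 0/1/NA vector with attribute `cutpoints`.
#' @export
cprs_flag <- function(closeness, conflict, weights = NULL, cutpoints = NULL) {
  f_clo <- quintile_flag(closeness, "bottom_one", weights = weights,
                         cutpoint = cutpoints$closeness)
  f_con <- quintile_flag(conflict, "top_one", weights = weights,
                         cutpoint = cutpoints$conflict)
  out <- as.integer(as.logical(f_clo) | as.logical(f_con))
  attr(out, "cutpoints") <- list(closeness = attr(f_clo, "cutpoint"),
                                 conflict = attr(f_con, "cutpoint"))
  out
}

#' Derive the binary analysis set from a raw cohort
#'
#' Applies the exposure, mediator, outcome and confounder codings to a raw
#' cohort table: equivalised-income bottom-two-quintile exposure `X`
#' (optionally the below-60%-of-median alternative), DASS top-quintile
#' mediator `M1`, CPRS-SF poor-relationship mediator `M2`, abnormal-SDQ
#' outcome `Y`, and the six binary confounders (low maternal education = no
#' or compulsory-only qualifications; low maternal age = under 20 at first
#' birth; maternal unemployment; more than four children; one-parent family;
#' ethnic minority).  The survey weight is carried through unchanged.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()] for the
#'   column dictionary).
#' @param cutpoints optional named list of fixed thresholds (`income`,
#'   `dass`, `closeness`, `conflict`) formed on a reference sample, e.g.
#'   `attr(cohort, "cutpoints")`.  Default `NULL`: quintiles are estimated
#'   within the supplied sample.
#' @param income_rule `"bottom_two_quintiles"` (default) or
#'   `"below_60pct_median"`.
#' @param weighted logical; use survey-weighted quantiles (default FALSE).
#' @return A data.frame of class `analysis_set` with columns `child_id`,
#'   `X`, `M1`, `M2`, `Y`, the six confounder flags, and weight `w`
#'   (0/1/NA coding); attribute `confounders` names the confounder columns.
#' @export
derive_analysis_set <- function(cohort, cutpoints = NULL,
                                income_rule = c("bottom_two_quintiles",
                                                "below_60pct_median"),
                                weighted = FALSE) {
  income_rule <- match.arg(income_rule)
  need <- c("hh_income", "n_adults", "n_other_14plus", "n_children_u14",
            paste0("dass_", 1:6), "closeness", "conflict", "sdq_total",
            "maternal_education", "maternal_age_band", "unemployed",
            "n_children_band", "one_parent", "ethnic_minority", "weight")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  w <- if (weighted) cohort$weight else NULL

  eq_inc <- oecd_equivalise(cohort$hh_income, cohort$n_adults,
                            cohort$n_other_14plus, cohort$n_children_u14)
  X <- if (income_rule == "bottom_two_quintiles") {
    quintile_flag(eq_inc, "bottom_two", weights = w, cutpoint = cutpoints$income)
  } else {
    med <- stats::median(eq_inc, na.rm = TRUE)
    out <- ifelse(is.na(eq_inc), NA_integer_, as.integer(eq_inc < 0.6 * med))
    attr(out, "cutpoint") <- 0.6 * med
    out
  }
  M1 <- dass_flag(cohort[paste0("dass_", 1:6)], weights = w,
                  cutpoint = cutpoints$dass)
  M2 <- cprs_flag(cohort$closeness, cohort$conflict, weights = w,
                  cutpoints = cutpoints[c("closeness", "conflict")])
  Y <- attr(sdq_band(cohort$sdq_total), "flag")

  as_int <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x))
  out <- data.frame(
    child_id = cohort$child_id,
    X = as.integer(X), M1 = as.integer(M1), M2 = as.integer(M2), Y = Y,
    low_educ = as_int(ifelse(is.na(cohort$maternal_education), NA,
                             cohort$maternal_education %in%
                               c("standard_grade", "no_qualifications"))),
    low_mat_age = as_int(cohort$maternal_age_band == "<20"),
    unemployed = as_int(cohort$unemployed),
    children_4plus = as_int(cohort$n_children_band == "4+"),
    one_parent = as_int(cohort$one_parent),
    ethnic_minority = as_int(cohort$ethnic_minority),
    w = cohort$weight)
  attr(out, "confounders") <- c("low_educ", "low_mat_age", "unemployed",
                                "children_4plus", "one_parent", "ethnic_minority")
  attr(out, "cutpoints_used") <- list(
    income = attr(X, "cutpoint"), dass = attr(M1, "cutpoint"),
    cprs = attr(M2, "cutpoints"))
  class(out) <- c("analysis_set", "data.frame")
  out
}
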