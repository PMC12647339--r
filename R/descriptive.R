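#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' Computes `OR = (a d)/(b c)` with the log-normal (Woolf) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  Zero cells trigger a
#' +0.5 continuity correction of all cells, with a warning.
#'
#' @param a,b,c,d cell counts: exposed-flagged, exposed-unflagged,
#'   unexposed-flagged, unexposed-unflagged.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return Object of class `or_result` with fields `a`, `b`, `c`, `d`,
#'   `or_`, `ci_low`, `ci_high`, `alpha`.  Display output rounds half-up to
#'   2 decimals.
#' @export
#' @examples
#' two_by_two_or(433, 983, 409, 1814)  # 1.95 (1.67 to 2.28)
two_by_two_or <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    warning("zero cell: applying +0.5 continuity correction to all cells")
    cells <- cells + 0.5
  }
  or_ <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(a = a, b = b, c = c, d = d, or_ = unname(or_),
                 ci_low = unname(or_ * exp(-z * se)),
                 ci_high = unname(or_ * exp(z * se)),
                 alpha = alpha),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f to %.2f) [%g%% CI]\n",
              round_half_up(x$or_), round_half_up(x$ci_low),
              round_half_up(x$ci_high), 100 * (1 - x$alpha)))
  invisible(x)
}

#' Exposure-stratified prevalence and odds-ratio table
#'
#' For each binary flag in `variables`, tabulates the flagged count and
#' percentage within the exposed (`X == 1`) and unexposed strata and the
#' odds ratio (with Woolf CI) of being flagged for exposed vs unexposed --
#' the layout of an exposure-stratified descriptive table.  Percentages use
#' the stratum sizes (including rows where the flag itself is missing is
#' *not* done: rows with a missing flag are dropped per variable).
#'
#' @param analysis_set data.frame with binary `X` and the listed flags.
#' @param variables character vector of flag column names.
#' @param denominators optional named vector `c(exposed =, unexposed =)`
#'   overriding the per-variable complete-case stratum sizes (e.g. imputed
#'   sample sizes).
#' @return data.frame: `variable`, `n_exposed`, `pct_exposed`,
#'   `n_unexposed`, `pct_unexposed`, `or_`, `ci_low`, `ci_high`.
#' @export
exposure_stratified_table <- function(analysis_set, variables,
                                      denominators = NULL) {
  X <- analysis_set$X
  if (all(stats::na.omit(X) == 0) || all(stats::na.omit(X) == 1)) {
    stop("empty stratum: both exposure groups are required")
  }
  rows <- lapply(variables, function(v) {
    f <- analysis_set[[v]]
    ok <- !is.na(f) & !is.na(X)
    a <- sum(f[ok] == 1 & X[ok] == 1)
    c_ <- sum(f[ok] == 1 & X[ok] == 0)
    n1 <- if (!is.null(denominators)) denominators[["exposed"]] else sum(X[ok] == 1)
    n0 <- if (!is.null(denominators)) denominators[["unexposed"]] else sum(X[ok] == 0)
    orr <- two_by_two_or(a, n1 - a, c_, n0 - c_)
    data.frame(variable = v, n_exposed = a, pct_exposed = 100 * a / n1,
               n_unexposed = c_, pct_unexposed = 100 * c_ / n0,
               or_ = orr$or_, ci_low = orr$ci_low, ci_high = orr$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample characteristics before and after imputation
#'
#' Builds a per-category count/percentage table of the survey sample
#' (complete cases per variable, missing counted separately) next to the
#' pooled imputed sample (counts averaged over the `m` completed data
#' sets), mirroring a before/after-imputation characteristics table.
#'
#' @param cohort the original data.frame.
#' @param imputation_set optional [chained_impute()] result on the same
#'   table; omitted, the imputed columns repeat the survey columns.
#' @param variables columns to summarise (default: all factor/binary).
#' @return data.frame: `variable`, `category`, `n_survey`, `pct_survey`,
#'   `n_missing`, `n_imputed`, `pct_imputed`.
#' @export
sample_characteristics <- function(cohort, imputation_set = NULL,
                                   variables = NULL) {
  if (is.null(variables)) {
    variables <- names(cohort)[vapply(cohort, function(col) {
      is.factor(col) || all(stats::na.omit(unique(as.numeric(col))) %in% c(0, 1))
    }, logical(1))]
  }
  imps <- if (is.null(imputation_set)) list(cohort) else imputation_set$imputations
  rows <- list()
  for (v in variables) {
    col <- cohort[[v]]
    cats <- if (is.factor(col)) levels(col) else c("1", "0")
    nmiss <- sum(is.na(col))
    nobs <- sum(!is.na(col))
    for (cat_ in cats) {
      n_s <- sum(as.character(col) == cat_, na.rm = TRUE)
      n_i <- mean(vapply(imps, function(d) sum(as.character(d[[v]]) == cat_,
                                               na.rm = TRUE), numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, category = cat_,
        n_survey = n_s, pct_survey = 100 * n_s / nobs, n_missing = nmiss,
        n_imputed = n_i, pct_imputed = 100 * n_i / nrow(cohort),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
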