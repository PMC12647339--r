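# Shared fixtures and independent oracles, all built in code.

zero_rates <- function() {
  r <- structural_params()$missing_rates
  r[] <- 0
  r
}

quick_params <- function(n, seed, ...) {
  structural_params(n_children = n, seed = seed, missing_rates = zero_rates(), ...)
}

# all causal paths out of X removed
params_zero_paths <- function(n, seed) {
  p <- quick_params(n, seed)
  p$alpha_M1["X"] <- 0; p$alpha_M2["X"] <- 0; p$alpha_Y["X"] <- 0
  p
}

complete_aset <- function(n, seed, params = quick_params(n, seed)) {
  co <- generate_cohort(params, inject_missing = FALSE)
  derive_analysis_set(co, cutpoints = attr(co, "cutpoints"))
}

# Independent closed-form oracle: marginal counterfactual probabilities by
# exhaustive enumeration of the confounder patterns (no Monte Carlo, no
# package internals beyond the parameter object itself).
analytic_effects <- function(params) {
  prev <- params$conf_prevalences
  k <- length(prev)
  Cg <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(Cg) <- names(prev)
  pC <- apply(Cg, 1, function(r) prod(ifelse(r == 1, prev, 1 - prev)))
  lp <- function(alpha, x = NULL, m1 = NULL, m2 = NULL) {
    out <- alpha[["intercept"]] + drop(Cg %*% alpha[colnames(Cg)])
    if (!is.null(x)) out <- out + alpha[["X"]] * x
    if (!is.null(m1) && "M1" %in% names(alpha)) out <- out + alpha[["M1"]] * m1
    if (!is.null(m2) && "M2" %in% names(alpha)) out <- out + alpha[["M2"]] * m2
    out
  }
  pM1 <- function(x) plogis(lp(params$alpha_M1, x = x))
  pM2 <- function(x, m1) plogis(lp(params$alpha_M2, x = x, m1 = m1))
  pY <- function(x, m1, m2) plogis(lp(params$alpha_Y, x = x, m1 = m1, m2 = m2))
  cf <- function(x0, x1, x2) {
    p1y <- pM1(x1); p1m <- pM1(x2)
    p2 <- (1 - p1m) * pM2(x2, 0) + p1m * pM2(x2, 1)
    tot <- (1 - p1y) * (1 - p2) * pY(x0, 0, 0) + (1 - p1y) * p2 * pY(x0, 0, 1) +
      p1y * (1 - p2) * pY(x0, 1, 0) + p1y * p2 * pY(x0, 1, 1)
    sum(pC * tot)
  }
  odds <- function(p) p / (1 - p)
  p000 <- cf(0, 0, 0); p100 <- cf(1, 0, 0); p110 <- cf(1, 1, 0); p111 <- cf(1, 1, 1)
  c(nde = log(odds(p100) / odds(p000)), nie_m1 = log(odds(p110) / odds(p100)),
    nie_m2 = log(odds(p111) / odds(p110)),
    nie_joint = log(odds(p111) / odds(p100)), te = log(odds(p111) / odds(p000)))
}

# 10-row hand-checkable cohort with fixed reference cut-offs
toy_cutpoints <- function() list(income = 10000, dass = 12L,
                                 closeness = 24L, conflict = 24L, sdq = 17L)

toy_cohort <- function() {
  d <- data.frame(
    child_id = 1:10,
    hh_income = c(21000, 20000, NA, 13500, 5000, 42000, 15000, 16000, 17000, 18000),
    n_adults = c(2, 1, 2, 1, 1, 2, 2, 2, 2, 2),
    n_other_14plus = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
    n_children_u14 = c(2, 1, 1, 1, 1, 3, 1, 1, 1, 1),
    dass_1 = c(0, 3, 2, NA, 3, 0, 1, 0, 0, 0),
    dass_2 = c(0, 3, 0, 0, 3, 0, 1, 0, 0, 0),
    dass_3 = c(0, 3, 0, 0, 3, 0, 0, 0, 0, 0),
    dass_4 = c(0, 2, 0, 0, 3, 0, 0, 0, 0, 0),
    dass_5 = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    dass_6 = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    closeness = c(35, 24, 30, 25, 7, 33, NA, NA, 30, 31),
    conflict = c(8, 10, 24, 23, 40, 9, 30, 8, 10, 11),
    sdq_total = c(0, 17, 16, 14, 40, NA, 5, 6, 7, 8),
    maternal_education = factor(
      c("degree_or_vocational", "no_qualifications", "higher",
        "degree_or_vocational", "standard_grade", "degree_or_vocational",
        "higher", "degree_or_vocational", "degree_or_vocational",
        "standard_grade"),
      levels = c("degree_or_vocational", "higher", "standard_grade",
                 "no_qualifications")),
    maternal_age_band = factor(
      c("30-39", "<20", "20-29", "30-39", "20-29", "30-39", "30-39",
        "20-29", "30-39", "40+"),
      levels = c("<20", "20-29", "30-39", "40+")),
    unemployed = c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    n_children_band = factor(
      c("2-3", "1", "1", "1", "1", "2-3", "1", "1", "1", "1"),
      levels = c("1", "2-3", "4+")),
    one_parent = c(0, 1, 0, 1, 1, 0, 0, 0, 0, 0),
    ethnic_minority = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 1),
    weight = c(1, 1, 1, 1, 1, 1, 1, 1, 2.5, 1))
  d
}

# hand-derived expectations for toy_cohort() under toy_cutpoints():
#  eq income: 21000/2.1=10000 (X=1), 20000/1.3 (0), NA, 13500/1.3 (0), 5000/1.3 (1),
#             42000/2.9=14482.8 (0), 15000/1.8=8333.3 (1), 8888.9 (1),
#             9444.4 (1), 10000 (1)
#  dass sums: 0,13,2,NA,12,0,2,0,0,0 -> M1 0,1,0,NA,1,0,0,0,0,0
#  M2: clo<=24 | con>=24: 0,1,1,0,1,0,(NA|1)=1,(NA|0)=NA,0,0
#  Y (sdq>=17): 0,1,0,0,1,NA,0,0,0,0
toy_expected <- function() {
  list(X = c(1L, 0L, NA, 0L, 1L, 0L, 1L, 1L, 1L, 1L),
       M1 = c(0L, 1L, 0L, NA, 1L, 0L, 0L, 0L, 0L, 0L),
       M2 = c(0L, 1L, 1L, 0L, 1L, 0L, 1L, NA, 0L, 0L),
       Y = c(0L, 1L, 0L, 0L, 1L, NA, 0L, 0L, 0L, 0L),
       low_educ = c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L),
       low_mat_age = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
}

# one-binary-confounder analysis set for g-formula equivalence
onec_aset <- function(n, seed) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  X <- rbinom(n, 1, plogis(-1 + z))
  M1 <- rbinom(n, 1, plogis(-1 + 0.5 * X + 0.6 * z))
  M2 <- rbinom(n, 1, plogis(-0.8 + 0.4 * X + 0.7 * M1 + 0.3 * z))
  Y <- rbinom(n, 1, plogis(-2 + 0.8 * X + 0.5 * M1 + 0.6 * M2 + 0.4 * z))
  d <- data.frame(X = X, M1 = M1, M2 = M2, Y = Y, z = z, w = 1)
  attr(d, "confounders") <- "z"
  class(d) <- c("analysis_set", "data.frame")
  d
}

# correlated multivariate-normal table with MCAR holes
mvn_mcar_table <- function(n, rate, seed, p = 4, mar_on = NULL, mar_coef = 1.5) {
  set.seed(seed)
  S <- 0.5^abs(outer(1:p, 1:p, "-"))
  L <- chol(S)
  Y <- matrix(rnorm(n * p), n, p) %*% L
  colnames(Y) <- paste0("v", 1:p)
  Y <- as.data.frame(Y)
  if (is.null(mar_on)) {
    for (j in seq_len(p)) Y[[j]][runif(n) < rate] <- NA
  } else {
    # missingness of v1 depends on (fully observed) v2
    pmis <- plogis(qlogis(rate) + mar_coef * Y[[mar_on]])
    Y[[1]][runif(n) < pmis] <- NA
  }
  Y
}
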