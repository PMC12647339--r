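#' Little's test of missing completely at random
#'
#' Tests whether per-missingness-pattern observed means are consistent with
#' a single multivariate-normal mean/covariance estimated by EM, the
#' classical chi-square MCAR test.  All variables are coerced to numeric
#' (factors by their level codes), so binary/ordinal variables are handled
#' under the normal approximation -- the convention of the widespread SPSS
#' implementation; the result is approximate for discrete data.
#'
#' The statistic is `sum_j n_j (ybar_obs,j - mu_obs,j)' Sigma_obs,j^{-1}
#' (ybar_obs,j - mu_obs,j)` over missingness patterns `j`, with
#' `df = sum_j p_j - p` (observed-variable counts minus total variables),
#' referred to a chi-square distribution.  Rows with every variable missing
#' carry no information and are dropped.
#'
#' @param table data.frame with >= 2 variables.
#' @param max_iter,tol EM iteration controls.
#' @param ridge_eps ridge added to a singular observed-block covariance
#'   (applied with a warning).
#' @return Object of class `mcar_test`: `chi2`, `df`, `p`, `n_patterns`,
#'   `applicable` (FALSE for complete data, where df = 0 and the test is
#'   reported "not applicable").
#' @export
littles_mcar_test <- function(table, max_iter = 200, tol = 1e-7,
                              ridge_eps = 1e-6) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  Ymat <- sapply(table, function(col) as.numeric(if (is.factor(col)) unclass(col) else col))
  Ymat <- matrix(Ymat, nrow = nrow(table), dimnames = list(NULL, names(table)))
  keep <- rowSums(!is.na(Ymat)) > 0
  Ymat <- Ymat[keep, , drop = FALSE]
  n <- nrow(Ymat); p <- ncol(Ymat)
  R <- !is.na(Ymat)
  if (all(R)) {
    return(structure(list(chi2 = 0, df = 0L, p = NA_real_, n_patterns = 1L,
                          applicable = FALSE), class = "mcar_test"))
  }

  pat_id <- apply(R, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_id)

  em <- em_mvnorm(Ymat, R, pats, max_iter, tol, ridge_eps)
  mu <- em$mu; Sigma <- em$Sigma

  chi2 <- 0; df <- 0L
  ridged <- FALSE
  for (rows in pats) {
    obs <- which(R[rows[1], ])
    if (length(obs) == 0) next
    nj <- length(rows)
    ybar <- colMeans(Ymat[rows, obs, drop = FALSE])
    d <- ybar - mu[obs]
    Soo <- Sigma[obs, obs, drop = FALSE]
    inv <- tryCatch(solve(Soo), error = function(e) NULL)
    if (is.null(inv)) {
      ridged <- TRUE
      inv <- solve(Soo + diag(ridge_eps * mean(diag(Soo)), length(obs)))
    }
    chi2 <- chi2 + nj * drop(t(d) %*% inv %*% d)
    df <- df + length(obs)
  }
  df <- df - p
  if (ridged) warning("singular observed-block covariance; ridge-regularised with eps = ",
                      ridge_eps)
  structure(list(chi2 = chi2, df = as.integer(df),
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n_patterns = length(pats), applicable = TRUE),
            class = "mcar_test")
}

#' @export
print.mcar_test <- function(x, ...) {
  if (!x$applicable) {
    cat("Little's MCAR test: not applicable (no incomplete rows; df = 0)\n")
  } else {
    cat(sprintf("Little's MCAR test: chi2 = %.3f, df = %d, p = %.4g (%d patterns)\n",
                x$chi2, x$df, x$p, x$n_patterns))
  }
  invisible(x)
}

# EM for multivariate normal mean/covariance with arbitrary missingness,
# computed pattern-by-pattern (rows grouped by missingness pattern).
em_mvnorm <- function(Ymat, R, pats, max_iter, tol, ridge_eps) {
  n <- nrow(Ymat); p <- ncol(Ymat)
  mu <- colMeans(Ymat, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  Sigma <- stats::cov(Ymat, use = "pairwise.complete.obs")
  Sigma[is.na(Sigma)] <- 0
  diag(Sigma)[diag(Sigma) <= 0] <- 1
  Sigma <- Sigma + diag(1e-6 * mean(diag(Sigma)), p)

  for (it in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    for (rows in pats) {
      obs <- which(R[rows[1], ]); mis <- which(!R[rows[1], ])
      Yo <- Ymat[rows, obs, drop = FALSE]
      nj <- length(rows)
      if (length(mis) == 0) {
        S1[obs] <- S1[obs] + colSums(Yo)
        S2[obs, obs] <- S2[obs, obs] + crossprod(Yo)
        next
      }
      Soo <- Sigma[obs, obs, drop = FALSE]
      inv <- tryCatch(solve(Soo), error = function(e)
        solve(Soo + diag(ridge_eps * mean(diag(Soo)), length(obs))))
      B <- Sigma[mis, obs, drop = FALSE] %*% inv
      resid <- sweep(Yo, 2, mu[obs])
      Em <- matrix(mu[mis], nj, length(mis), byrow = TRUE) + resid %*% t(B)
      Cm <- Sigma[mis, mis, drop = FALSE] - B %*% Sigma[obs, mis, drop = FALSE]
      if (length(obs)) {
        S1[obs] <- S1[obs] + colSums(Yo)
        S2[obs, obs] <- S2[obs, obs] + crossprod(Yo)
        S2[obs, mis] <- S2[obs, mis] + crossprod(Yo, Em)
        S2[mis, obs] <- t(S2[obs, mis, drop = FALSE])
      }
      S1[mis] <- S1[mis] + colSums(Em)
      S2[mis, mis] <- S2[mis, mis] + crossprod(Em) + nj * Cm
    }
    mu_new <- S1 / n
    Sigma_new <- S2 / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma))
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol) break
  }
  list(mu = mu, Sigma = Sigma, iterations = it)
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells by cycling per-variable conditional models: logistic
#' regression for binary variables, nested binary logits for factors with
#' more than two levels, and predictive-mean-matching (5 donors, type-1
#' matching) for continuous/integer variables.  Every other analysis
#' variable enters each conditional model.  One independent chain is run
#' per imputation, initialised by random draws from the observed marginals,
#' cycled `n_iterations` times with the last iterate kept.  Parameter draws
#' come from the approximate normal posterior of each fit, so imputations
#' are proper.  Conditional models showing separation fall back to a weakly
#' penalised fit with a warning.
#'
#' @param table data.frame to impute; every incomplete variable must have
#'   at least one observed value.
#' @param m number of imputations.
#' @param n_iterations chained-equation cycles per imputation.
#' @param seed master seed; per-chain streams are derived from it.
#' @return Object of class `imputation_set`: list with `imputations` (m
#'   completed data.frames), `m`, `n_iterations`, `seed`, `methods`
#'   (per-variable labels), and `trace` (chain means of imputed cells,
#'   iterations x variables x chains).
#' @export
chained_impute <- function(table, m = 20, n_iterations = 50, seed = 1L) {
  stopifnot(is.data.frame(table), m >= 1, n_iterations >= 1)
  vars <- names(table)
  n_missing <- vapply(table, function(col) sum(is.na(col)), integer(1))
  if (any(vapply(table, function(col) all(is.na(col)), logical(1)))) {
    stop("variable with zero observed values cannot be imputed")
  }
  methods <- vapply(vars, function(v) impute_method(table[[v]]), character(1))
  incomplete <- vars[n_missing > 0]

  if (length(incomplete) == 0) {
    return(structure(list(imputations = replicate(m, table, simplify = FALSE),
                          m = m, n_iterations = n_iterations, seed = seed,
                          methods = methods, trace = NULL),
                     class = "imputation_set"))
  }

  seeds <- derive_seeds(seed, m)
  trace <- array(NA_real_, dim = c(n_iterations, length(incomplete), m),
                 dimnames = list(NULL, incomplete, NULL))
  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(seeds[k])
    cur <- table
    for (v in incomplete) {  # init from observed marginals
      nas <- is.na(cur[[v]])
      cur[[v]][nas] <- sample(cur[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(n_iterations)) {
      for (v in incomplete) {
        nas <- is.na(table[[v]])
        Xm <- stats::model.matrix(~ ., data = cur[setdiff(vars, v)])
        cur[[v]][nas] <- impute_draw(table[[v]][!nas], Xm[!nas, , drop = FALSE],
                                     Xm[nas, , drop = FALSE], methods[[v]])
        trace[it, v, k] <- mean(as.numeric(cur[[v]][nas]))
      }
    }
    imputations[[k]] <- cur
  }
  structure(list(imputations = imputations, m = m, n_iterations = n_iterations,
                 seed = seed, methods = methods, trace = trace),
            class = "imputation_set")
}

impute_method <- function(col) {
  if (is.factor(col)) {
    if (nlevels(col) <= 2) "logreg" else "polyreg"
  } else {
    u <- unique(col[!is.na(col)])
    if (length(u) <= 2 && all(u %in% c(0, 1))) "logreg" else "pmm"
  }
}

# one conditional-model draw for the missing cells of a variable
impute_draw <- function(y_obs, X_obs, X_mis, method) {
  if (nrow(X_mis) == 0) return(y_obs[0])
  if (method == "logreg") {
    lv <- if (is.factor(y_obs)) levels(y_obs) else NULL
    y01 <- if (is.factor(y_obs)) as.integer(y_obs == lv[2]) else as.integer(y_obs)
    fit <- fit_logit(X_obs, y01)
    beta <- draw_beta(fit, X_obs, rep(1, nrow(X_obs)))
    draw <- stats::rbinom(nrow(X_mis), 1L, stats::plogis(drop(X_mis %*% beta)))
    if (is.null(lv)) draw else factor(lv[draw + 1L], levels = lv)
  } else if (method == "polyreg") {
    lv <- levels(y_obs)
    K <- length(lv)
    out <- rep(NA_integer_, nrow(X_mis))
    active_obs <- rep(TRUE, length(y_obs))
    active_mis <- rep(TRUE, nrow(X_mis))
    for (j in seq_len(K - 1)) {   # nested binary logits: level j vs later
      oj <- active_obs & !is.na(y_obs)
      if (sum(oj) == 0 || !any(active_mis)) break
      yj <- as.integer(y_obs[oj] == lv[j])
      if (length(unique(yj)) < 2) {
        pj <- rep(mean(yj), sum(active_mis))
      } else {
        fit <- fit_logit(X_obs[oj, , drop = FALSE], yj)
        beta <- draw_beta(fit, X_obs[oj, , drop = FALSE], rep(1, sum(oj)))
        pj <- stats::plogis(drop(X_mis[active_mis, , drop = FALSE] %*% beta))
      }
      take <- stats::runif(length(pj)) < pj
      out[which(active_mis)[take]] <- j
      active_mis[which(active_mis)[take]] <- FALSE
      active_obs <- active_obs & (y_obs != lv[j])
    }
    out[is.na(out)] <- K
    factor(lv[out], levels = lv)
  } else {  # pmm
    y <- as.numeric(y_obs)
    XtX <- crossprod(X_obs)
    XtXi <- tryCatch(solve(XtX), error = function(e)
      solve(XtX + diag(1e-6 * mean(diag(XtX)), ncol(XtX))))
    beta_hat <- drop(XtXi %*% crossprod(X_obs, y))
    res <- y - drop(X_obs %*% beta_hat)
    dfres <- max(length(y) - ncol(X_obs), 1)
    sigma2 <- sum(res^2) / stats::rchisq(1, dfres)
    L <- tryCatch(chol(XtXi * sigma2), error = function(e)
      chol(XtXi * sigma2 + diag(1e-10, ncol(XtXi))))
    beta_star <- beta_hat + drop(t(L) %*% stats::rnorm(ncol(X_obs)))
    pred_obs <- drop(X_obs %*% beta_hat)
    pred_mis <- drop(X_mis %*% beta_star)
    donors <- vapply(pred_mis, function(pm) {
      idx <- order(abs(pred_obs - pm))[seq_len(min(5, length(pred_obs)))]
      y[sample(idx, 1)]
    }, numeric(1))
    if (is.integer(y_obs)) as.integer(donors) else donors
  }
}

#' Compare observed and imputed distributions
#'
#' Per-variable diagnostic mirroring a before/after-imputation table:
#' mean (or level proportion) of observed cells vs imputed cells pooled
#' across the `m` imputations, their standardised difference, and a
#' two-sample test p-value (Welch t-test for continuous variables,
#' proportion test for binary/factor levels).  Variables with no missing
#' cells report a standardised difference of exactly 0.
#'
#' @param original the data.frame that was imputed.
#' @param imputation_set result of [chained_impute()].
#' @return data.frame with one row per variable (per level for factors):
#'   `variable`, `level`, `n_missing`, `mean_observed`, `mean_imputed`,
#'   `std_diff`, `p_value`.
#' @export
compare_imputed <- function(original, imputation_set) {
  stopifnot(inherits(imputation_set, "imputation_set"),
            identical(names(original), names(imputation_set$imputations[[1]])))
  rows <- list()
  for (v in names(original)) {
    nas <- is.na(original[[v]])
    obs <- original[[v]][!nas]
    imp <- unlist(lapply(imputation_set$imputations,
                         function(d) as.character(d[[v]][nas])), use.names = FALSE)
    if (is.factor(original[[v]])) {
      for (lv in levels(original[[v]])) {
        po <- mean(obs == lv)
        pi_ <- if (length(imp)) mean(imp == lv) else po
        rows[[length(rows) + 1]] <- diag_row(v, lv, sum(nas), po, pi_,
                                             n_obs = length(obs),
                                             n_imp = length(imp), binary = TRUE)
      }
    } else {
      obs_n <- as.numeric(obs)
      imp_n <- if (length(imp)) as.numeric(imp) else numeric(0)
      mo <- mean(obs_n)
      mi <- if (length(imp_n)) mean(imp_n) else mo
      binary <- all(stats::na.omit(unique(as.numeric(original[[v]]))) %in% c(0, 1))
      rows[[length(rows) + 1]] <- diag_row(v, NA, sum(nas), mo, mi,
                                           n_obs = length(obs_n),
                                           n_imp = length(imp_n), binary = binary,
                                           obs_vec = obs_n, imp_vec = imp_n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

diag_row <- function(v, lv, n_missing, mo, mi, n_obs, n_imp, binary,
                     obs_vec = NULL, imp_vec = NULL) {
  if (n_imp == 0) {
    sd_diff <- 0; pval <- NA_real_
  } else if (binary || !is.null(lv) && is.na(lv) == FALSE) {
    pbar <- (mo * n_obs + mi * n_imp) / (n_obs + n_imp)
    sd_diff <- if (pbar <= 0 || pbar >= 1) 0 else (mi - mo) / sqrt(pbar * (1 - pbar))
    pval <- tryCatch(suppressWarnings(stats::prop.test(
      c(round(mo * n_obs), round(mi * n_imp)), c(n_obs, n_imp))$p.value),
      error = function(e) NA_real_)
  } else {
    sp <- sqrt((stats::var(obs_vec) + stats::var(imp_vec)) / 2)
    sd_diff <- if (sp == 0) 0 else (mi - mo) / sp
    pval <- tryCatch(stats::t.test(obs_vec, imp_vec)$p.value,
                     error = function(e) NA_real_)
  }
  data.frame(variable = v, level = if (is.null(lv)) NA_character_ else lv,
             n_missing = n_missing, mean_observed = mo, mean_imputed = mi,
             std_diff = sd_diff, p_value = pval, stringsAsFactors = FALSE)
}
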