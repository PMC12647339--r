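#' @keywords internal
"_PACKAGE"

# Weighted empirical-CDF quantile: smallest observed value v with Fw(v) >= q.
# Ties at the cut are included by construction ("<= cut" flagging downstream).
weighted_quantile_cut <- function(values, q, weights = NULL) {
  ok <- !is.na(values)
  v <- values[ok]
  if (is.null(weights)) w <- rep(1, length(v)) else {
    w <- weights[ok]
    if (anyNA(w) || any(w <= 0)) stop("weights must be positive and non-missing")
  }
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  idx <- which(cw >= q - 1e-12)[1L]
  v[idx]
}

# Deterministic sub-stream seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Logistic (or fractional-logistic) fit on a model matrix with an automatic
# weakly penalised fallback when the ML fit separates or fails to converge.
# Separation is flagged by non-convergence or runaway coefficients.
# A lean IRLS handles the full-rank case; rank-deficient designs (e.g.
# saturated models with empty cells) fall back to glm.fit's pivoting.
fit_logit <- function(X, y, w = NULL, ridge = 0, max_abs_beta = 15) {
  if (is.null(w)) w <- rep(1, length(y))
  if (ridge > 0) return(ridge_logit(X, y, w, ridge))
  fit <- tryCatch(irls_logit(X, y, w, max_abs_beta), error = function(e) NULL)
  bad <- FALSE
  if (is.null(fit)) {
    fit <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                           family = quasibinomial()))
    cf <- fit$coefficients[!is.na(fit$coefficients)]
    bad <- !fit$converged || any(!is.finite(cf)) ||
      any(abs(cf[names(cf) != colnames(X)[1]]) > max_abs_beta)
  } else if (fit$separated) {
    bad <- TRUE
  }
  if (bad) {
    warning("separation or non-convergence in logistic fit; using weakly penalised fit",
            call. = FALSE)
    fit <- ridge_logit(X, y, w, 1e-2)
  }
  fit
}

# plain IRLS maximum-likelihood logistic fit; errors on singular designs;
# glm-style relative-deviance convergence
irls_logit <- function(X, y, w, max_abs_beta = 15, max_iter = 25, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis((sum(w * y) + 0.5) / (sum(w) + 1))
  converged <- FALSE
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    Wv <- w * v
    Ch <- chol(crossprod(X, X * Wv))   # error here => caller falls back
    rhs <- crossprod(X, Wv * (eta + (y - mu) / v))
    beta <- drop(backsolve(Ch, forwardsolve(t(Ch), rhs)))
    if (!all(is.finite(beta)) || max(abs(beta)) > 1e4) break
    mu <- stats::plogis(drop(X %*% beta))
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(w * (y * log(mu_c) + (1 - y) * log(1 - mu_c)))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  mu <- stats::plogis(drop(X %*% beta))
  list(coefficients = stats::setNames(beta, colnames(X)),
       fitted.values = mu, converged = converged,
       separated = !converged || any(abs(beta[-1]) > max_abs_beta))
}

# IRLS ridge logistic regression (intercept unpenalised).
ridge_logit <- function(X, y, w, lambda, max_iter = 100, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p)); pen[1, 1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wirls <- w * mu * (1 - mu)
    wirls[wirls < 1e-10] <- 1e-10
    z <- eta + (y - mu) / (mu * (1 - mu) + 1e-10)
    XtW <- t(X * wirls)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  XtW <- t(X * (w * mu * (1 - mu)))
  list(coefficients = stats::setNames(beta, colnames(X)),
       fitted.values = mu, converged = TRUE, penalised = TRUE,
       cov_unscaled = solve(XtW %*% X + pen))
}

# Covariance of coefficients for a glm.fit result (binomial dispersion = 1).
logit_vcov <- function(fit, X, w) {
  if (!is.null(fit$cov_unscaled)) return(fit$cov_unscaled)
  mu <- fit$fitted.values
  info <- t(X * (w * mu * (1 - mu))) %*% X
  ridge <- 1e-8 * mean(diag(info))
  tryCatch(solve(info), error = function(e) solve(info + diag(ridge, ncol(X))))
}

# Draw coefficients from the approximate normal posterior of a logistic fit.
draw_beta <- function(fit, X, w) {
  V <- logit_vcov(fit, X, w)
  V <- (V + t(V)) / 2
  L <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8, ncol(V))))
  drop(fit$coefficients + t(L) %*% stats::rnorm(ncol(V)))
}

round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
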