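## Gaussian linear mixed models with nested grouping, fitted by REML through
## nlme::lme (diagonal or multiple-of-identity random-effect covariances,
## ARMA within-group correlation, constant-plus-power variance function),
## plus the diagnostic arithmetic used on them: information criteria,
## likelihood-ratio tests, conditional t-tests, Cholesky-whitened residuals
## and pooled empirical autocorrelation functions.

#' ARMA within-group correlation specification
#' @param p,q autoregressive and moving-average orders.
#' @export
corr_arma <- function(p = 1L, q = 1L) {
  stopifnot(p >= 0, q >= 0, p + q > 0)
  structure(list(p = as.integer(p), q = as.integer(q)), class = "corr_arma")
}

#' Random-effects structure specifications
#'
#' \code{rand_diag} gives each random covariate its own standard deviation
#' (diagonal covariance); \code{rand_ident} shares a single standard
#' deviation across all covariates (a multiple of the identity).
#'
#' @param covariates character vector of random-effect covariate expressions
#'   (an intercept is always included); NULL keeps the formula's default.
#' @export
rand_diag <- function(covariates = NULL)
  structure(list(kind = "diag", covariates = covariates), class = "rand_spec")

#' @rdname rand_diag
#' @export
rand_ident <- function(covariates = NULL)
  structure(list(kind = "ident", covariates = covariates), class = "rand_spec")

## ---- fitting ---------------------------------------------------------------

#' Fit a detrending model specification by REML
#'
#' Maximizes the restricted likelihood of the Gaussian linear mixed model
#' described by a \code{\link{td_form}}/\code{\link{lme_form}} specification
#' on a processed multilevel series. With no grouping levels the model
#' degenerates to ordinary least squares.
#'
#' @param spec a \code{growth_formula} specification.
#' @param data a \code{hier_series} (processed growth or aridity table).
#' @param control optional \code{nlme::lmeControl} list.
#' @return A \code{fitted_lmm} object: fixed-effect table, variance
#'   components, log-likelihood, residuals (raw and normalized), fitted
#'   values and group counts.
#' @export
fit_reml <- function(spec, data, control = NULL) {
  rs <- resolve_spec(spec, data)
  df <- as.data.frame(data)
  used <- stats::complete.cases(df[unique(c(rs$resp_var, rs$covar_vars,
                                            rs$groups))])
  df <- df[used, , drop = FALSE]
  for (g in rs$groups) df[[g]] <- factor(df[[g]])
  fixed <- stats::as.formula(paste(rs$response, "~",
                                   paste(rs$covariates, collapse = " + ")))
  mf <- stats::model.frame(fixed, df, na.action = stats::na.pass)
  if (any(!is.finite(as.matrix(mf))))
    stop("non-finite values after transformation (e.g. log of a ",
         "non-positive increment or cumulative value)", call. = FALSE)
  corr <- if (!is.null(rs$correlation))
    nlme::corARMA(p = rs$correlation$p, q = rs$correlation$q)
  wts <- if (identical(rs$variance, "const_power")) nlme::varConstPower()
  if (length(rs$groups) == 0L) {
    fit <- stats::lm(fixed, data = df)
    return(wrap_lm(fit, rs, df))
  }
  ranform <- stats::as.formula(paste("~",
      paste(rs$random$covariates, collapse = " + ")))
  pd <- if (rs$random$kind == "ident") nlme::pdIdent(ranform)
        else nlme::pdDiag(ranform)
  random <- stats::setNames(rep(list(pd), length(rs$groups)), rs$groups)
  ctl <- do.call(nlme::lmeControl,
                 utils::modifyList(list(maxIter = 100L, msMaxIter = 200L,
                                        returnObject = FALSE),
                                   as.list(control %||% list())))
  ## quasi-Newton first; simplex-seeded optim as fallback when the surface
  ## is awkward (e.g. near-singular variance components under ARMA errors)
  fit <- tryCatch(
    nlme::lme(fixed, data = df, random = random, correlation = corr,
              weights = wts, method = rs$method, control = ctl),
    error = function(e1) tryCatch({
      ctl2 <- ctl; ctl2$opt <- "optim"
      nlme::lme(fixed, data = df, random = random, correlation = corr,
                weights = wts, method = rs$method, control = ctl2)
    }, error = function(e2)
      stop("REML fit failed: ", conditionMessage(e1), call. = FALSE)))
  wrap_lme(fit, rs, df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wrap_lme <- function(fit, rs, df) {
  ll <- stats::logLik(fit)
  sm <- summary(fit)
  tt <- as.data.frame(sm$tTable)
  names(tt) <- c("estimate", "se", "df", "t", "p")
  innermost <- length(rs$groups)
  structure(list(
    engine = fit,
    spec = rs,
    beta = tt,
    loglik = as.numeric(ll),
    k = as.integer(attr(ll, "df")),
    N = fit$dims$N,
    p = nrow(tt),
    n_groups = utils::head(fit$dims$ngrps, length(rs$groups)),
    sigma = fit$sigma,
    varcomps = nlme::VarCorr(fit),
    fitted = stats::fitted(fit, level = innermost),
    resid_raw = stats::resid(fit, level = innermost, type = "response"),
    resid_norm = stats::resid(fit, level = innermost, type = "normalized"),
    blups = nlme::ranef(fit),
    data = df), class = "fitted_lmm")
}

wrap_lm <- function(fit, rs, df) {
  sm <- summary(fit)
  tt <- as.data.frame(sm$coefficients)
  tt$df <- fit$df.residual
  tt <- tt[c(1L, 2L, 5L, 3L, 4L)]
  names(tt) <- c("estimate", "se", "df", "t", "p")
  ## restricted log-likelihood, so comparisons against REML fits are coherent
  ll <- stats::logLik(fit, REML = TRUE)
  structure(list(
    engine = fit,
    spec = rs,
    beta = tt,
    loglik = as.numeric(ll),
    k = as.integer(attr(ll, "df")),
    N = length(fit$residuals),
    p = nrow(tt),
    n_groups = integer(0),
    sigma = sm$sigma,
    varcomps = NULL,
    fitted = stats::fitted(fit),
    resid_raw = stats::resid(fit),
    resid_norm = stats::resid(fit) / sm$sigma,
    blups = NULL,
    data = df), class = "fitted_lmm")
}

#' @export
print.fitted_lmm <- function(x, ...) {
  cat("Linear", if (length(x$n_groups)) "mixed-effects" else "(OLS)",
      "model fit by", x$spec$method, "\n")
  ic <- info_criteria(x)
  cat(sprintf("  AIC %.4f  BIC %.4f  logLik %.4f  (k = %d, N = %d)\n",
              ic$AIC, ic$BIC, ic$logLik, x$k, x$N))
  cat("Fixed effects:", deparse(stats::formula(x$engine)), "\n")
  print(round(x$beta, 6))
  if (length(x$n_groups)) {
    cat("Groups:\n"); print(x$n_groups)
  }
  invisible(x)
}

#' @export
summary.fitted_lmm <- function(object, ...) {
  if (inherits(object$engine, "lme")) summary(object$engine)
  else summary(object$engine)
}

#' @export
logLik.fitted_lmm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$N - object$p,
            class = "logLik")
}

## ---- diagnostics -----------------------------------------------------------

#' Information criteria of a restricted-likelihood fit
#'
#' AIC = -2 logLik + 2 k, and BIC = -2 logLik + k log(N - p), where k counts
#' all estimated parameters (fixed effects, variance/correlation parameters
#' and the residual standard deviation) and N - p is the effective sample
#' size of the restricted likelihood (observations minus fixed-effect
#' coefficients).
#'
#' @param object a \code{fitted_lmm}, or the log-likelihood value.
#' @param k,n,p parameter count, observations and fixed-effect count, used
#'   when \code{object} is a bare log-likelihood.
#' @return list(AIC, BIC, logLik).
#' @export
info_criteria <- function(object, k = NULL, n = NULL, p = NULL) {
  if (inherits(object, "fitted_lmm")) {
    ll <- object$loglik; k <- object$k; n <- object$N; p <- object$p
  } else ll <- as.numeric(object)
  out <- list(AIC = -2 * ll + 2 * k, logLik = ll)
  out$BIC <- if (!is.null(n)) -2 * ll + k * log(n - p) else NA_real_
  out[c("AIC", "BIC", "logLik")]
}

#' Likelihood-ratio test between two nested fits
#'
#' @param big,small \code{fitted_lmm} objects, or lists with elements
#'   \code{loglik} and \code{k}; \code{big} must have more parameters.
#' @return list(l_ratio, df, p).
#' @export
lr_test <- function(big, small) {
  lb <- big$loglik; kb <- big$k
  ls <- small$loglik; ks <- small$k
  if (kb <= ks) stop("'big' must have more parameters than 'small'",
                     call. = FALSE)
  if (inherits(big, "fitted_lmm") && inherits(small, "fitted_lmm") &&
      big$spec$method == "REML" &&
      !identical(big$spec$covariates, small$spec$covariates))
    warning("restricted likelihoods are not strictly comparable across ",
            "different fixed-effect structures", call. = FALSE)
  stat <- 2 * (lb - ls)
  df <- kb - ks
  list(l_ratio = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Conditional t-tests of the fixed effects
#'
#' t = estimate/SE per coefficient, with denominator degrees of freedom from
#' the containment rule of the nested grouping (observations minus groups at
#' the level where the covariate varies), and two-sided p-values.
#'
#' @param model a \code{fitted_lmm}.
#' @return data.frame(estimate, se, df, t, p), one row per coefficient.
#' @export
cond_t_tests <- function(model) model$beta

#' Conditional t statistic from an estimate/standard-error pair
#' @param estimate,se coefficient estimate and its standard error.
#' @param df denominator degrees of freedom.
#' @return list(t, p) with the two-sided p-value.
#' @export
t_marginal <- function(estimate, se, df) {
  t <- estimate / se
  list(t = t, p = 2 * stats::pt(-abs(t), df = df))
}

#' Stationary ARMA autocorrelation matrix
#'
#' Toeplitz matrix of the theoretical autocorrelation function of a
#' stationary ARMA(p, q) process; ARMA(1, 1) decays exponentially for lags
#' >= 2, ARMA(1, 0) gives rho(l) = phi^l, white noise gives the identity.
#'
#' @param phi AR coefficients (all roots of the AR polynomial outside the
#'   unit circle).
#' @param theta MA coefficients.
#' @param n series length (matrix dimension).
#' @return n x n correlation matrix.
#' @export
arma_corr <- function(phi = numeric(0), theta = numeric(0), n) {
  if (length(phi) &&
      any(Mod(polyroot(c(1, -phi))) <= 1 + 1e-10))
    stop("non-stationary AR parameters", call. = FALSE)
  if (length(phi) == 0L && length(theta) == 0L) return(diag(n))
  ac <- stats::ARMAacf(ar = phi, ma = theta, lag.max = n - 1L)
  stats::toeplitz(as.numeric(ac))
}

#' Constant-plus-power standard-deviation multipliers
#'
#' Per-observation residual SD multipliers rho1 + |nu|^rho2 evaluated at the
#' fitted values nu; squared and scaled by sigma^2 they give the residual
#' variance Var(e) = sigma^2 (rho1 + |nu|^rho2)^2.
#'
#' @param rho1 non-negative constant.
#' @param rho2 power.
#' @param fitted fitted values nu.
#' @return Numeric vector of multipliers (must all be positive).
#' @export
var_const_power <- function(rho1, rho2, fitted) {
  if (rho1 < 0) stop("rho1 must be non-negative", call. = FALSE)
  m <- rho1 + abs(fitted)^rho2
  if (any(m <= 0))
    stop("zero variance multiplier (rho1 = 0 and fitted value 0)",
         call. = FALSE)
  m
}

#' Whiten a residual vector with a within-group covariance matrix
#'
#' Forward-solves the lower Cholesky factor of R against the raw residuals;
#' under a correctly specified model the result is approximately white with
#' unit variance.
#'
#' @param R within-group residual variance-covariance (or correlation)
#'   matrix, positive definite.
#' @param resid raw residual vector of matching length.
#' @return Normalized residual vector.
#' @export
whiten_residuals <- function(R, resid) {
  L <- tryCatch(t(chol(R)), error = function(e)
    stop("residual covariance is not positive definite", call. = FALSE))
  as.numeric(forwardsolve(L, resid))
}

#' Normalized residuals of a fitted model
#'
#' Residuals whitened per innermost group with the Cholesky factor of the
#' estimated within-group covariance (correlation structure, variance
#' function and sigma). When the estimated covariance is sigma^2 I these are
#' the raw residuals divided by sigma.
#'
#' @param model a \code{fitted_lmm}.
#' @return Numeric vector of normalized residuals, in data order.
#' @export
normalize_residuals <- function(model) as.numeric(model$resid_norm)

#' Pooled empirical autocorrelation of grouped residuals
#'
#' The lag-l autocorrelation pooled across groups:
#' rho(l) = [sum_c sum_t e_{c,t} e_{c,t-l} / N(l)] / [sum_c sum_t e_{c,t}^2 / N(0)],
#' with N(l) the number of residual pairs at lag l, plus two-sided normal
#' critical bounds +/- z_{1-alpha/2} / sqrt(N(l)).
#'
#' @param resid numeric residual vector.
#' @param groups innermost-group labels (same length as \code{resid});
#'   residuals must be time-ordered within group.
#' @param max_lag maximum lag (must be positive and shorter than the longest
#'   group).
#' @param alpha significance level of the critical bounds (default 0.05).
#' @return data.frame(lag, acf, n_pairs, bound); rho(0) is always 1.
#' @export
acf_resid <- function(resid, groups, max_lag = 10L, alpha = 0.05) {
  if (max_lag <= 0L) stop("max_lag must be positive", call. = FALSE)
  parts <- split(as.numeric(resid), groups)
  if (max_lag >= max(lengths(parts)))
    stop("max_lag must be smaller than the longest group", call. = FALSE)
  num <- den <- npair <- numeric(max_lag + 1L)
  for (e in parts) {
    n <- length(e)
    for (l in 0:min(max_lag, n - 1L)) {
      num[l + 1L] <- num[l + 1L] + sum(e[(1L + l):n] * e[1:(n - l)])
      npair[l + 1L] <- npair[l + 1L] + (n - l)
    }
  }
  scaled <- num / npair
  data.frame(lag = 0:max_lag,
             acf = scaled / scaled[1L],
             n_pairs = npair,
             bound = stats::qnorm(1 - alpha / 2) / sqrt(npair))
}
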