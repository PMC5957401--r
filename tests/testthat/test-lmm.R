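test_that("balanced one-way REML matches the closed-form ANOVA oracle", {
  set.seed(11)
  g <- 8L; n <- 6L
  grp <- rep(sprintf("g%d", 1:g), each = n)
  y <- rep(rnorm(g, sd = 1.2), each = n) + rnorm(g * n, sd = 0.7)
  hs <- hier_series(data.frame(y = y, year = rep(2001:(2000 + n), g),
                               grp = grp, stringsAsFactors = FALSE),
                    values = "y", times = "year", factors = "grp")
  fit <- fit_reml(lme_form(resp = "y", covar = "1",
                           random = rand_diag("1")), hs)
  ## intercept-only random structure: ~1 | grp
  m <- tapply(y, grp, mean)
  MSW <- sum((y - m[grp])^2) / (g * n - g)
  MSB <- sum(n * (m - mean(y))^2) / (g - 1)
  sb2 <- max(0, (MSB - MSW) / n)
  expect_equal(fit$sigma^2, MSW, tolerance = 1e-6)
  sd_b <- suppressWarnings(as.numeric(fit$varcomps[1, 2]))
  expect_equal(sd_b^2, sb2, tolerance = 1e-6)
  expect_equal(fit$beta$estimate[1], mean(y), tolerance = 1e-8)

  ## profiled likelihood equals a direct dense-matrix REML evaluation
  ll <- reml_loglik_oneway(y, factor(grp), sd_b, fit$sigma)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("with no grouping the fit degenerates to exact least squares", {
  set.seed(12)
  d <- data.frame(y = rnorm(30), year = rep(2001:2010, 3),
                  grp = rep(c("a", "b", "c"), each = 10),
                  stringsAsFactors = FALSE)
  hs <- hier_series(d, values = "y", times = "year", factors = "grp")
  fit <- fit_reml(lme_form(resp = "y", covar = "year", lev_rm = "grp"), hs)
  ols <- lm(y ~ year, data = d)
  expect_equal(fit$beta$estimate, unname(coef(ols)))
  expect_equal(fit$beta$se, unname(sqrt(diag(vcov(ols)))))
  expect_equal(fit$loglik, as.numeric(logLik(ols, REML = TRUE)))
})

test_that("wrong covariate names are reported", {
  hs <- hier_series(data.frame(y = 1:6, year = rep(1:3, 2),
                               grp = rep(c("a", "b"), each = 3),
                               stringsAsFactors = FALSE),
                    values = "y", times = "year", factors = "grp")
  expect_error(fit_reml(lme_form(resp = "nope"), hs), "unknown column")
})

test_that("ARMA autocorrelation matrices follow the closed forms", {
  ## AR(1) reduction
  M <- arma_corr(phi = 0.6, n = 5)
  expect_equal(M[1, ], 0.6^(0:4))
  ## ARMA(1,1): rho(1) = (1 + phi theta)(phi + theta)/(1 + 2 phi theta + theta^2)
  phi <- 0.5; theta <- 0.3
  r1 <- (1 + phi * theta) * (phi + theta) / (1 + 2 * phi * theta + theta^2)
  A <- arma_corr(phi = phi, theta = theta, n = 4)
  expect_equal(A[1, 2], r1, tolerance = 1e-10)
  expect_equal(A[1, 3], phi * r1, tolerance = 1e-10)
  expect_equal(round(A[1, 2], 5), 0.66187)
  ## white noise
  expect_equal(arma_corr(n = 3), diag(3))
  expect_error(arma_corr(phi = 1.01, n = 3), "non-stationary")
})

test_that("constant-plus-power variance multipliers evaluate Eq-style cases", {
  expect_equal(var_const_power(2, 0, fitted = c(-4, 7)), c(3, 3))
  expect_equal(var_const_power(0, 1, fitted = 3), 3)
  expect_equal(var_const_power(2, 0.5, fitted = 9), 5)
  expect_error(var_const_power(0, 1, fitted = 0), "multiplier")
  expect_error(var_const_power(-1, 1, fitted = 1), "non-negative")
})

test_that("whitening solves the lower Cholesky factor", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  z <- whiten_residuals(R, c(1, 1))
  expect_equal(z, c(1, 1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(round(z[2], 5), 0.57735)
  ## R = sigma^2 I: normalized = raw / sigma
  expect_equal(whiten_residuals(4 * diag(3), c(2, -2, 4)), c(1, -1, 2))
  expect_error(whiten_residuals(matrix(c(1, 2, 2, 1), 2), c(1, 1)),
               "positive definite")
})

test_that("information criteria and LR tests reproduce their identities", {
  ic <- info_criteria(0, k = 0, n = 10, p = 1)
  expect_equal(ic$AIC, 0)
  ic2 <- info_criteria(-100, k = 5, n = 104, p = 4)
  expect_equal(ic2$AIC, 210)
  expect_equal(ic2$BIC, 200 + 5 * log(100))

  same <- list(loglik = -50, k = 4)
  big <- list(loglik = -50, k = 6)
  lr <- lr_test(big, same)
  expect_equal(lr$l_ratio, 0)
  expect_equal(lr$p, 1)
  expect_error(lr_test(same, big), "more parameters")
  ## chi-square df 2 upper tail is exp(-x/2)
  lr2 <- lr_test(list(loglik = -10, k = 5), list(loglik = -11, k = 3))
  expect_equal(lr2$p, exp(-1))
})

test_that("criteria agree with stats::AIC/BIC on a real REML fit", {
  set.seed(13)
  g <- gen_growth(sim_design(years = 1966:2005), seed = 13)
  pr <- recursive_eval(g$series, fns = c("rtimes", "scacum"),
                       lvs = c("tree", "sample"))
  fit <- fit_quiet(fit_reml(td_form(), pr))
  ic <- info_criteria(fit)
  expect_equal(ic$AIC, AIC(fit$engine), tolerance = 1e-8)
  expect_equal(ic$BIC, BIC(fit$engine), tolerance = 1e-8)
  expect_equal(fit$k, attr(logLik(fit$engine), "df"))
  ## t table is estimate/se with containment df
  tt <- cond_t_tests(fit)
  expect_equal(tt$t, tt$estimate / tt$se, tolerance = 1e-12)
  tm <- t_marginal(tt$estimate[2], tt$se[2], tt$df[2])
  expect_equal(tm$t, tt$t[2])
  expect_equal(tm$p, tt$p[2], tolerance = 1e-12)
})

test_that("pooled residual ACF matches direct computation and bounds", {
  set.seed(14)
  e <- rnorm(40)
  one <- acf_resid(e, rep("a", 40), max_lag = 5)
  expect_equal(one$acf[1], 1)
  ## single group: compare to the plain biased ACF with N(l) scaling
  l <- 2
  num <- sum(e[(1 + l):40] * e[1:(40 - l)]) / (40 - l)
  den <- sum(e^2) / 40
  expect_equal(one$acf[l + 1], num / den, tolerance = 1e-12)
  expect_equal(one$bound, qnorm(0.975) / sqrt(one$n_pairs))

  ## AR(1) with phi = 0.7: rho_hat(1) near 0.7 at n = 2000
  set.seed(15)
  ar <- as.numeric(arima.sim(list(ar = 0.7), n = 2000))
  a <- acf_resid(ar, rep("a", 2000), max_lag = 3)
  expect_lt(abs(a$acf[2] - 0.7), 0.05)

  ## white noise across groups stays inside 1% bounds at almost all lags
  set.seed(16)
  wn <- rnorm(8 * 125)
  gid <- rep(sprintf("g%d", 1:8), each = 125)
  w <- acf_resid(wn, gid, max_lag = 10, alpha = 0.01)
  expect_gte(sum(abs(w$acf[-1]) < w$bound[-1]), 9L)
  expect_error(acf_resid(wn, gid, max_lag = 0), "positive")
  expect_error(acf_resid(wn, gid, max_lag = 125), "longest group")
})

test_that("ACF pooling matches nlme's empirical ACF on a fitted model", {
  set.seed(17)
  g <- gen_growth(sim_design(years = 1976:2005), seed = 17)
  frame <- fit_quiet(model_frame(g$series))
  mine <- acf_fluc(frame, max_lag = 5, res_type = "normalized")
  ref <- nlme::ACF(frame$model$engine, maxLag = 5, resType = "normalized")
  expect_equal(mine$acf, ref$ACF, tolerance = 1e-8)
})

test_that("normalized residuals whiten simulated AR(1) errors", {
  set.seed(18)
  d <- sim_design(years = 1881:2005, phi = 0.6, theta = 0)
  g <- gen_growth(d, seed = 18)
  frame <- fit_quiet(model_frame(g$series, correlation = corr_arma(1, 0)))
  a <- acf_fluc(frame, max_lag = 5, alpha = 0.01, res_type = "normalized")
  expect_lt(abs(a$acf[2]), a$bound[2])
  ## raw residuals of the same fit stay visibly autocorrelated
  raw <- acf_fluc(frame, max_lag = 5, alpha = 0.01, res_type = "raw")
  expect_gt(raw$acf[2], a$acf[2])
})
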