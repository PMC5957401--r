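## Seeded generators of growth and climate fixtures with the statistical
## structure of the multilevel log-linear growth model and a Mediterranean
## seasonal climate cycle, emulating a nested sampling design of two plots
## x two trees x two cores observed over ~125 years.

#' Simulation design for synthetic dendroclimatic series
#'
#' The growth generator draws nested random effects (plot, tree, core) for
#' the intercept, the log-cumulative-growth slope and the time slope of the
#' log-linear growth model, then iterates the growth recursion year by year
#' on the log-increment scale; the model equation is exactly the
#' data-generating process, so detrending it is well posed. The climate
#' generator overlays a sinusoidal seasonal cycle (temperature peaking in
#' July, precipitation in winter: a Mediterranean regime with summer
#' drought), linear annual trends and seeded noise, per plot.
#'
#' @param n_plots,n_trees,n_cores plots, trees per plot, cores per tree.
#' @param years calendar years of the ring record (>= 10).
#' @param beta fixed-effect coefficients (intercept, log(csx) slope, f(t)
#'   slope); the default gives rings around a millimeter and cumulative
#'   radii on the order of 100-300 mm over 125 years.
#' @param log_t logical; generate with f(t) = log(t) instead of f(t) = t.
#' @param sd_plot,sd_tree,sd_core random-effect SDs per level, each a
#'   3-vector (intercept, log(csx), f(t)).
#' @param sigma residual SD on the log scale (~ relative ring-width noise).
#' @param phi,theta optional ARMA(1,1) parameters of the residual process
#'   (0, 0 = white noise).
#' @param truncate_rings inner rings dropped from every core, emulating
#'   cores that miss the pith (the reference radii still measure the full
#'   cumulative growth, exercising the additive rescaling path).
#' @param climate_years calendar years of the monthly climate record; the
#'   default spans the 51 calendar years giving 50 complete seasonal years.
#' @param t_mean,t_amp,t_trend,t_sd monthly temperature mean, seasonal
#'   amplitude (deg C), linear trend (deg C/yr) and noise SD.
#' @param p_mean,p_amp,p_trend,p_sd monthly precipitation mean, seasonal
#'   amplitude (mm), linear trend (mm/yr) and noise SD (truncated at 0).
#' @return A \code{sim_design} list.
#' @export
sim_design <- function(n_plots = 2L, n_trees = 2L, n_cores = 2L,
                       years = 1881:2005,
                       beta = c(-0.8, 0.5, -0.02), log_t = FALSE,
                       sd_plot = c(0.12, 0.008, 0.0015),
                       sd_tree = c(0.08, 0.006, 0.001),
                       sd_core = c(0.04, 0.004, 0.0008),
                       sigma = 0.2, phi = 0, theta = 0,
                       truncate_rings = 0L,
                       climate_years = 1955:2005,
                       t_mean = 12, t_amp = 8, t_trend = 0.02, t_sd = 1,
                       p_mean = 40, p_amp = 30, p_trend = 0, p_sd = 12) {
  stopifnot(length(years) >= 10L, length(beta) == 3L,
            all(c(sd_plot, sd_tree, sd_core) >= 0), sigma >= 0,
            abs(phi) < 1, beta[2L] < 1)
  as.list(environment())
}

## one core's ring series: solve the implicit per-year equation
## log(x_t) = b0 + b1 log(csx_{t-1} + x_t) + b2 f(t) + e_t
## by fixed point (contraction for b1 < 1); at t = 1 the cumulative seeds
## itself, giving the closed form log(x_1) = (b0 + b2 f(1) + e_1)/(1 - b1).
sim_core <- function(b, ftime, eps) {
  n <- length(eps)
  x <- numeric(n)
  csx <- 0
  for (t in seq_len(n)) {
    c0 <- b[1L] + b[3L] * ftime[t] + eps[t]
    if (csx == 0) {
      xt <- exp(c0 / (1 - b[2L]))
    } else {
      xt <- exp(c0 + b[2L] * log(csx))
      for (it in 1:60) {
        new <- exp(c0 + b[2L] * log(csx + xt))
        if (abs(new - xt) < 1e-12 * max(new, 1e-12)) { xt <- new; break }
        xt <- new
      }
    }
    x[t] <- xt
    csx <- csx + xt
  }
  x
}

#' Generate a synthetic multilevel ring-width series with tree radii
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return list(series, radii, rf_t): a growth \code{hier_series} (value
#'   \code{x} in mm), the named tree radius vector (full cumulative growth,
#'   mm) and its measurement year.
#' @export
gen_growth <- function(design = sim_design(), seed = NULL) {
  d <- design
  with_seed(seed, {
    years <- d$years
    n <- length(years)
    ftime <- if (d$log_t) log(seq_len(n)) else seq_len(n)
    recs <- list()
    rad <- numeric(0)
    for (ip in seq_len(d$n_plots)) {
      pcode <- paste0("P", 100 + ip)
      u_p <- stats::rnorm(3L, 0, d$sd_plot)
      for (it in seq_len(d$n_trees)) {
        tcode <- as.character(it)
        u_t <- stats::rnorm(3L, 0, d$sd_tree)
        finals <- numeric(d$n_cores)
        for (ic in seq_len(d$n_cores)) {
          ccode <- letters[ic]
          u_c <- stats::rnorm(3L, 0, d$sd_core)
          b <- d$beta + u_p + u_t + u_c
          eps <- if (d$phi != 0 || d$theta != 0) {
            as.numeric(stats::arima.sim(
              model = list(ar = if (d$phi != 0) d$phi else NULL,
                           ma = if (d$theta != 0) d$theta else NULL),
              n = n, sd = d$sigma))
          } else stats::rnorm(n, 0, d$sigma)
          x <- sim_core(b, ftime, eps)
          if (any(!is.finite(x)))
            stop("design produced non-finite growth", call. = FALSE)
          finals[ic] <- sum(x)
          keep <- seq_len(n) > d$truncate_rings
          recs[[length(recs) + 1L]] <- data.frame(
            x = x[keep], year = years[keep], sample = ccode,
            tree = tcode, plot = pcode, stringsAsFactors = FALSE)
        }
        ## the measured radius is the full cross-section: no core exceeds it
        rad[paste(pcode, tcode, sep = ".")] <- max(finals)
      }
    }
    series <- hier_series(do.call(rbind, recs), values = "x",
                          times = "year",
                          factors = c("sample", "tree", "plot"))
    list(series = series, radii = radii(rad), rf_t = max(years))
  })
}

#' Generate paired synthetic wide climate tables
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return list(prec, temp): wide data.frames (year rownames, plot.Mon
#'   columns) that round-trip through \code{\link{parse_wide_climate}}.
#' @export
gen_climate <- function(design = sim_design(), seed = NULL) {
  d <- design
  with_seed(seed, {
    years <- d$climate_years
    cols_p <- list(); cols_t <- list()
    for (ip in seq_len(d$n_plots)) {
      pcode <- paste0("P", 100 + ip)
      off_t <- stats::rnorm(1L, 0, 0.5)
      off_p <- stats::rnorm(1L, 0, 5)
      for (m in 1:12) {
        tm <- d$t_mean + off_t + d$t_amp * cos(2 * pi * (m - 7) / 12) +
          d$t_trend * (years - years[1L]) +
          stats::rnorm(length(years), 0, d$t_sd)
        pm <- pmax(0, d$p_mean + off_p + d$p_amp * cos(2 * pi * (m - 1) / 12) +
          d$p_trend * (years - years[1L]) +
          stats::rnorm(length(years), 0, d$p_sd))
        cols_t[[paste(pcode, month.abb[m], sep = ".")]] <- tm
        cols_p[[paste(pcode, month.abb[m], sep = ".")]] <- pm
      }
    }
    prec <- as.data.frame(cols_p, check.names = FALSE)
    temp <- as.data.frame(cols_t, check.names = FALSE)
    rownames(prec) <- rownames(temp) <- years
    list(prec = prec, temp = temp)
  })
}
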