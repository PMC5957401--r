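## Formula builders and the model-frame orchestration: chain the one-level
## routines over a multilevel series, fit the detrending model by REML, and
## extract the within-group fluctuations.

#' Growth-theory time-decline detrending formula
#'
#' Builds the log-linear growth specification log(x) ~ log(csx) + f(t) with
#' the full factor hierarchy (minus \code{lev_rm}) as nested random-effect
#' levels. With \code{log_t = FALSE} f(t) = t (a time-decline,
#' Chapman-Richards-like form); with \code{log_t = TRUE} f(t) = log(t) (a
#' logarithmic time-decline, Levakovic-like form). With
#' \code{on_time = FALSE} calendar year replaces relative time.
#'
#' @param on_time logical; use the relative \code{time} column (TRUE) or the
#'   calendar \code{year} (FALSE).
#' @param log_t logical; f(t) = log(t) instead of f(t) = t.
#' @param lev_rm factors to remove from the grouping term (innermost ones
#'   are typically dropped to pool their variability), or NULL.
#' @param random optional \code{\link{rand_diag}}/\code{\link{rand_ident}}
#'   structure; default: diagonal covariance over the formula covariates.
#' @param correlation optional \code{\link{corr_arma}} within-group
#'   correlation.
#' @param variance NULL or \code{"const_power"} for a constant-plus-power
#'   residual variance function.
#' @param method estimation method, "REML" (default) or "ML".
#' @return A \code{growth_formula} specification.
#' @export
td_form <- function(on_time = TRUE, log_t = FALSE, lev_rm = NULL,
                    random = NULL, correlation = NULL, variance = NULL,
                    method = "REML") {
  structure(list(type = "td", on_time = isTRUE(on_time),
                 log_t = isTRUE(log_t), lev_rm = lev_rm,
                 resp = NULL, covar = NULL,
                 random = random, correlation = correlation,
                 variance = variance, method = method),
            class = "growth_formula")
}

#' Linear mixed-effects detrending formula
#'
#' Builds the linear specification resp ~ covar with the factor hierarchy
#' (minus \code{lev_rm}) as nested random-effect levels; used e.g. to
#' subtract the weak linear trend of square-root aridity indexes.
#'
#' @param resp response column name; NULL uses the first measurement column.
#' @param covar covariate column name(s); NULL uses the first time column.
#' @inheritParams td_form
#' @return A \code{growth_formula} specification.
#' @export
lme_form <- function(resp = NULL, covar = NULL, lev_rm = NULL,
                     random = NULL, correlation = NULL, variance = NULL,
                     method = "REML") {
  structure(list(type = "lme", on_time = NULL, log_t = NULL,
                 lev_rm = lev_rm, resp = resp, covar = covar,
                 random = random, correlation = correlation,
                 variance = variance, method = method),
            class = "growth_formula")
}

## resolve a formula spec against the data: concrete response/covariate
## expressions, grouping levels (outermost first) and random structure
resolve_spec <- function(spec, data) {
  stopifnot(inherits(spec, "growth_formula"))
  fcts <- hs_factors(data)
  if (!is.null(spec$lev_rm)) {
    bad <- setdiff(spec$lev_rm, fcts)
    if (length(bad))
      stop("unknown factor(s) in lev_rm: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  groups <- rev(setdiff(fcts, spec$lev_rm))   # outermost first
  if (spec$type == "td") {
    xcol <- hs_values(data)[1L]
    tvar <- if (spec$on_time) "time" else "year"
    if (!tvar %in% names(data))
      stop("column '", tvar, "' not found (run rtimes first?)", call. = FALSE)
    if (!"csx" %in% names(data))
      stop("column 'csx' not found (run scacum first)", call. = FALSE)
    fterm <- if (spec$log_t) paste0("log(", tvar, ")") else tvar
    response <- paste0("log(", xcol, ")")
    covariates <- c("log(csx)", fterm)
    resp_var <- xcol; covar_vars <- c("csx", tvar)
  } else {
    resp_var <- spec$resp %||% hs_values(data)[1L]
    covar_vars <- spec$covar %||% hs_times(data)[length(hs_times(data))]
    covar_vars <- setdiff(covar_vars, "1")   # "1" = intercept-only model
    if (length(covar_vars) == 0L) {
      response <- resp_var
      rnd <- spec$random %||% rand_diag()
      if (is.null(rnd$covariates)) rnd$covariates <- "1"
      return(list(type = spec$type, response = resp_var, covariates = "1",
                  resp_var = resp_var, covar_vars = character(0),
                  groups = groups, random = rnd,
                  correlation = spec$correlation, variance = spec$variance,
                  method = spec$method))
    }
    missing <- setdiff(c(resp_var, covar_vars), names(data))
    if (length(missing))
      stop("unknown column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    response <- resp_var
    covariates <- covar_vars
  }
  rnd <- spec$random %||% rand_diag()
  if (is.null(rnd$covariates)) rnd$covariates <- covariates
  list(type = spec$type, response = response, covariates = covariates,
       resp_var = resp_var, covar_vars = covar_vars, groups = groups,
       random = rnd, correlation = spec$correlation,
       variance = spec$variance, method = spec$method)
}

## ---- model frames ----------------------------------------------------------

growth_defaults <- list(fn = c("rtimes", "scacum", "amod"),
                        lv = c("tree", "sample", "sample"))
climate_defaults <- list(fn = c("moveYr", "wlai"),
                         lv = c("year", "year"))

coerce_input <- function(rd) {
  if (inherits(rd, "hier_series")) return(rd)
  if (is.list(rd) && !is.data.frame(rd) && length(rd) == 2L)
    return(parse_wide_climate(rd[[1L]], rd[[2L]]))
  parse_wide_growth(rd)
}

is_climate_series <- function(hs) all(c("prec", "temp") %in% hs_values(hs))

#' Process, detrend and extract fluctuations of a multilevel series
#'
#' The one-stop pipeline: applies the one-level routine chain \code{fn}
#' (vectorized over the levels in \code{lv}), builds the detrending formula,
#' fits it by REML, and collects the within-group residual fluctuations.
#' For a growth series the defaults synchronize (\code{rtimes} per tree),
#' cumulate (\code{scacum} per core) and allometrically transform
#' (\code{amod} per core) the ring widths, then fit the time-decline
#' formula. For a climate input (a list of wide precipitation and
#' temperature tables) the defaults relabel seasonal years (\code{moveYr})
#' and compute square-root annual aridity indices (\code{wlai}), then fit
#' the linear formula AI ~ year.
#'
#' @param rd a growth \code{hier_series} or wide growth table, or a list of
#'   two wide climate tables (precipitation, temperature).
#' @param fn character vector of routine names; NULL for the defaults above.
#' @param lv matching vector of evaluation levels; NULL for the defaults.
#' @param more_args named list of routine arguments; named vectors are
#'   matched to groups by dot-joined code (e.g. tree radii for
#'   \code{sc_c}).
#' @param form detrending formula: "tdForm", "lmeForm" or a
#'   \code{growth_formula} object; NULL picks tdForm for growth and lmeForm
#'   for climate inputs.
#' @param only_dup,sc_c,rf_t,mp,to_cm,ini_mnt,sqt,npts routine arguments,
#'   passed to every evaluation group (see \code{\link{rtimes}},
#'   \code{\link{scacum}}, \code{\link{amod}}, \code{\link{move_yr}},
#'   \code{\link{wlai}}); \code{to_cm = TRUE} may also be given as
#'   \code{to = "cm"}.
#' @param on_time,log_t,lev_rm,resp,covar formula arguments (see
#'   \code{\link{td_form}} and \code{\link{lme_form}}).
#' @param random,correlation,variance,method model arguments (see
#'   \code{\link{td_form}}).
#' @param res_type fluctuations stored in the frame: "raw" within-group
#'   residuals (default) or "normalized".
#' @param control optional \code{nlme::lmeControl} overrides.
#' @return A \code{model_frame}: list with the fitted model in \code{model},
#'   the fluctuation table in \code{fluc}, and the fully resolved arguments
#'   in \code{call_args} (so \code{\link{update_frame}} is deterministic).
#' @export
model_frame <- function(rd, fn = NULL, lv = NULL, more_args = list(),
                        form = NULL,
                        only_dup = TRUE, sc_c = NA, rf_t = NA,
                        mp = c(1, 1), to_cm = FALSE, ini_mnt = "Oct",
                        sqt = TRUE, npts = 365L,
                        on_time = TRUE, log_t = FALSE, lev_rm = NULL,
                        resp = NULL, covar = NULL,
                        random = NULL, correlation = NULL, variance = NULL,
                        method = "REML", res_type = "raw", control = NULL) {
  call_args <- list(rd = rd, fn = fn, lv = lv, more_args = more_args,
                    form = form, only_dup = only_dup, sc_c = sc_c,
                    rf_t = rf_t, mp = mp, to_cm = to_cm, ini_mnt = ini_mnt,
                    sqt = sqt, npts = npts, on_time = on_time, log_t = log_t,
                    lev_rm = lev_rm, resp = resp, covar = covar,
                    random = random, correlation = correlation,
                    variance = variance, method = method,
                    res_type = res_type, control = control)
  data <- coerce_input(rd)
  climate <- is_climate_series(data)
  defs <- if (climate) climate_defaults else growth_defaults
  fn <- fn %||% defs$fn
  lv <- lv %||% defs$lv
  if (length(unlist(fn)) != length(unlist(lv)))
    stop("fn and lv must have the same length", call. = FALSE)
  base_args <- list(only_dup = only_dup, sc_c = sc_c, rf_t = rf_t, mp = mp,
                    to_cm = to_cm, ini_mnt = ini_mnt, sqt = sqt, npts = npts)
  ma <- utils::modifyList(base_args, more_args)
  processed <- recursive_eval(data, fns = fn, lvs = lv, more_args = ma)
  spec <- if (inherits(form, "growth_formula")) {
    form
  } else {
    switch(form %||% if (climate) "lmeForm" else "tdForm",
           tdForm = td_form(on_time = on_time, log_t = log_t,
                            lev_rm = lev_rm, random = random,
                            correlation = correlation, variance = variance,
                            method = method),
           lmeForm = lme_form(resp = resp, covar = covar, lev_rm = lev_rm,
                              random = random, correlation = correlation,
                              variance = variance, method = method),
           stop("unknown formula '", form, "'", call. = FALSE))
  }
  model <- fit_reml(spec, processed, control = control)
  out <- structure(list(model = model, fluc = NULL, call_args = call_args,
                        processed = processed), class = "model_frame")
  out$fluc <- fluctuations(out, res_type = res_type)
  out
}

#' Refit a model frame with changed arguments
#'
#' Re-runs \code{\link{model_frame}} with the frame's original (fully
#' resolved) arguments, overridden by the named arguments supplied here;
#' untouched arguments are preserved exactly, so updating with no changes
#' reproduces the frame.
#'
#' @param frame a \code{model_frame}.
#' @param ... named \code{model_frame} arguments to override.
#' @return A new \code{model_frame}.
#' @export
update_frame <- function(frame, ...) {
  changed <- list(...)
  if (length(changed)) {
    bad <- setdiff(names(changed), names(frame$call_args))
    if (length(bad) || is.null(names(changed)) || any(!nzchar(names(changed))))
      stop("unknown argument(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    for (nm in names(changed))            # assign directly: NULLs must stick
      frame$call_args[nm] <- changed[nm]
  }
  do.call(model_frame, frame$call_args)
}

#' @export
update.model_frame <- function(object, ...) update_frame(object, ...)

#' Extract detrended fluctuation series from a model frame
#'
#' One residual series per innermost group of the processed data, ordered by
#' year: raw within-group residuals, or residuals normalized by the Cholesky
#' factor of the estimated within-group covariance.
#'
#' @param frame a \code{model_frame}.
#' @param res_type "raw" or "normalized".
#' @return A \code{hier_series} with value column \code{fluc}.
#' @export
fluctuations <- function(frame, res_type = c("raw", "normalized")) {
  res_type <- match.arg(res_type,
                        choices = c("raw", "normalized", "n"))
  model <- frame$model
  df <- model$data
  fl <- if (res_type == "raw") model$resid_raw else model$resid_norm
  fcts <- hs_factors(frame$processed)
  tcol <- intersect(c("year"), names(df))
  out <- data.frame(fluc = as.numeric(fl), stringsAsFactors = FALSE)
  out[[tcol]] <- df[[tcol]]
  for (f in fcts) out[[f]] <- as.character(df[[f]])
  hs <- hier_series(out, values = "fluc", times = tcol, factors = fcts)
  ord <- do.call(order, c(rev(hs[fcts]), list(hs$year)))
  hier_series(as.data.frame(hs)[ord, , drop = FALSE], values = "fluc",
              times = tcol, factors = fcts)
}

#' Pooled autocorrelation of a frame's fluctuations
#'
#' Empirical autocorrelation of the frame's residual series pooled across
#' innermost groups, with two-sided critical bounds; use
#' \code{res_type = "normalized"} to check a fitted correlation structure.
#'
#' @param frame a \code{model_frame}.
#' @param max_lag maximum lag in years.
#' @param alpha significance level of the bounds.
#' @param res_type "raw" or "normalized" residuals.
#' @return data.frame(lag, acf, n_pairs, bound).
#' @export
acf_fluc <- function(frame, max_lag = 10L, alpha = 0.05,
                     res_type = c("raw", "normalized")) {
  res_type <- match.arg(res_type, choices = c("raw", "normalized", "n"))
  fl <- fluctuations(frame, res_type = res_type)
  groups <- do.call(paste, c(rev(fl[hs_factors(fl)]), sep = "."))
  acf_resid(fl$fluc, groups, max_lag = max_lag, alpha = alpha)
}

#' @export
print.model_frame <- function(x, ...) {
  cat("Model frame:", nrow(x$processed), "processed records,",
      nrow(x$fluc), "fluctuation records\n")
  print(x$model)
  invisible(x)
}

#' @export
summary.model_frame <- function(object, ...) summary(object$model)
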