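## Annual aridity indices from Walter-Lieth diagrams: the diagram plots
## monthly precipitation P against twice the monthly mean temperature
## (E = 2T, the conventional evaporation equivalent: 1 deg C of monthly
## temperature amounts to 2 mm/month of evaporation). The index is the ratio
## of the dry area (E above P) to the wet area (P above E) over the year.

wl_nodes <- function(v) {
  ## months at midpoints of unit intervals on [0, 12]; the curve is closed
  ## at the year edges by linear continuation between the December and
  ## January neighbors of the (seasonally ordered) year.
  edge <- (v[12L] + v[1L]) / 2
  list(x = c(0, seq_len(12L) - 0.5, 12), y = c(edge, v, edge))
}

trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Interpolated Walter-Lieth curves for one seasonal year
#'
#' Exports the precipitation and evaporation-equivalent (2T) curves linearly
#' interpolated on a common fine grid, as used by \code{\link{wlai}}; handy
#' for plotting a diagram with any generic graphics tool.
#'
#' @param prec 12 monthly precipitation sums (mm), in seasonal order.
#' @param temp 12 monthly mean temperatures (deg C), in seasonal order.
#' @param npts number of interpolation points across the year (default 365).
#' @return data.frame with columns \code{x} (month axis, 0..12), \code{prec}
#'   and \code{evap} (both mm).
#' @export
wl_curves <- function(prec, temp, npts = 365L) {
  if (length(prec) != 12L || length(temp) != 12L)
    stop("exactly 12 monthly values are required", call. = FALSE)
  if (any(!is.finite(prec)) || any(!is.finite(temp)))
    stop("non-finite climate values", call. = FALSE)
  np <- wl_nodes(prec); ne <- wl_nodes(2 * temp)
  ## augment the grid with the curve nodes and the P/E crossing points, so
  ## the trapezoid rule integrates the piecewise-linear curves exactly and
  ## the areas are invariant to the grid resolution
  dif <- ne$y - np$y
  cross <- numeric(0)
  for (i in seq_len(length(dif) - 1L))
    if (dif[i] * dif[i + 1L] < 0)
      cross <- c(cross, np$x[i] +
                   dif[i] / (dif[i] - dif[i + 1L]) * (np$x[i + 1L] - np$x[i]))
  xs <- sort(unique(c(seq(0, 12, length.out = npts), np$x, cross)))
  data.frame(x = xs,
             prec = stats::approx(np$x, np$y, xout = xs)$y,
             evap = stats::approx(ne$x, ne$y, xout = xs)$y)
}

#' Annual aridity index of a Walter-Lieth diagram
#'
#' Builds the P and E = 2T curves at month midpoints, interpolates both to a
#' common fine grid, and integrates (trapezoid rule) the dry area
#' (E exceeding P) and the wet area (P exceeding E). The index is
#' dry/wet: 0 for a fully humid year, large for arid years. When the wet
#' area is zero the index is undefined and NA is returned with a warning (an
#' arid plot must not abort a multi-plot run). No >100 mm precipitation-axis
#' compression is applied: the index compares P with 2T directly.
#'
#' @inheritParams wl_curves
#' @param sqt logical; return the square root of the index (the square-root
#'   transformed index is usually stationary; default TRUE).
#' @return A single number (dimensionless), or NA when the wet area is zero.
#' @export
wlai <- function(prec, temp, sqt = TRUE, npts = 365L) {
  cur <- wl_curves(prec, temp, npts = npts)
  dry <- trapz(cur$x, pmax(cur$evap - cur$prec, 0))
  wet <- trapz(cur$x, pmax(cur$prec - cur$evap, 0))
  if (wet <= 0) {
    warning("wet area is zero: aridity index undefined", call. = FALSE)
    return(NA_real_)
  }
  ai <- dry / wet
  if (isTRUE(sqt)) sqrt(ai) else ai
}

## routine-registry wrapper: one plot's (already seasonally relabeled)
## monthly series in, one AI record per complete seasonal year out.
wlai_group <- function(group, sqt = TRUE, npts = 365L) {
  df <- as.data.frame(group)
  ord_col <- if ("mseq" %in% names(df)) "mseq" else "month"
  fcts <- hs_factors(group)
  out <- lapply(split(df, df$year), function(yr) {
    if (nrow(yr) != 12L) return(NULL)      # incomplete seasonal year
    yr <- yr[order(yr[[ord_col]]), , drop = FALSE]
    rec <- data.frame(AI = wlai(yr$prec, yr$temp, sqt = sqt, npts = npts),
                      year = yr$year[1L], stringsAsFactors = FALSE)
    for (f in fcts) rec[[f]] <- yr[[f]][1L]
    rec
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no complete seasonal year in group", call. = FALSE)
  hier_series(res, values = "AI", times = "year", factors = fcts)
}

#' Aridity table from paired climate tables
#'
#' Convenience pipeline: parse/accept wide climate tables, relabel months by
#' seasonal year, and compute one (square-rooted) annual aridity index per
#' plot and seasonal year.
#'
#' @param prec,temp wide climate tables (see \code{\link{parse_wide_climate}})
#'   or a pre-parsed climate \code{hier_series} in \code{prec} with
#'   \code{temp} missing.
#' @param ini_mnt first month of the seasonal year (default "Oct").
#' @param sqt logical; square-root transform the index (default TRUE).
#' @param npts interpolation points per year (default 365).
#' @return A \code{hier_series} with columns \code{AI}, \code{year}, plus the
#'   climate factors (at most one record per plot and year).
#' @export
aridity_table <- function(prec, temp = NULL, ini_mnt = "Oct", sqt = TRUE,
                          npts = 365L) {
  clim <- if (inherits(prec, "hier_series")) prec
          else parse_wide_climate(prec, temp)
  recursive_eval(clim, fns = c("moveYr", "wlai"), lvs = c("year", "year"),
                 more_args = list(ini_mnt = ini_mnt, sqt = sqt, npts = npts))
}
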