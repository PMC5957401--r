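## One-level routines: functions evaluated independently within each level of
## one ecological factor (or within each whole-series group for time-indexed
## routines), chained by recursive_eval().

#' Relative-time synchronization of replicated series
#'
#' Adds a \code{time} column of relative times, computed from the pooled
#' earliest year of the evaluation group (typically a tree), so that the same
#' calendar year gets the same relative time in every replicate (core). With
#' \code{only_dup = TRUE}, records whose relative time occurs in only one
#' replicate are removed to avoid biasing the multilevel detrending; if all
#' computed times are unique (e.g. a single replicate) the filter is skipped.
#'
#' @param group a \code{hier_series} restricted to one evaluation group.
#' @param only_dup logical; keep only relative times replicated across series.
#' @return The group with a \code{time} column (positive integers).
#' @export
rtimes <- function(group, only_dup = TRUE) {
  if (nrow(group) == 0L) stop("empty evaluation group", call. = FALSE)
  df <- as.data.frame(group)
  df$time <- df$year - min(df$year) + 1L
  if (isTRUE(only_dup)) {
    ## one record per (core, year), so a duplicated time == present in >= 2 cores
    cnt <- table(df$time)
    if (any(cnt > 1L)) {          # ignored when every time is unique
      keep <- cnt[as.character(df$time)] > 1L
      df <- df[keep, , drop = FALSE]
    }
  }
  hs_rewrap(df, group, values = union(hs_values(group), "time"))
}

#' Scaled cumulative sums of one series
#'
#' Computes the running sum \code{csx} of the increments of one core, ordered
#' by year. When a scaling constant \code{sc_c} (e.g. a measured tree radius)
#' is given, the cumulative series is shifted additively so that it equals
#' \code{sc_c} at the reference year \code{rf_t} (default: the core's last
#' year). The additive offset preserves the increments exactly and models a
#' missing inner-ring radius as a constant.
#'
#' @param core a \code{hier_series} holding one series (one core).
#' @param sc_c scaling constant (same units as the increments), or NA for an
#'   unscaled cumulative sum.
#' @param rf_t reference year at which the cumulative sum equals \code{sc_c};
#'   NA uses the maximum year of the core.
#' @return The core with a \code{csx} column appended.
#' @export
scacum <- function(core, sc_c = NA, rf_t = NA) {
  df <- as.data.frame(core)
  df <- df[order(df$year), , drop = FALSE]
  x <- df[[hs_values(core)[1L]]]
  csx <- cumsum(x)
  if (!is.na(sc_c)) {
    if (!is.finite(sc_c) || sc_c <= 0)
      stop("scaling constant must be positive", call. = FALSE)
    if (is.na(rf_t)) rf_t <- max(df$year)
    i <- match(rf_t, df$year)
    if (is.na(i))
      stop("reference time ", rf_t, " outside the core's year range",
           call. = FALSE)
    csx <- csx + (sc_c - csx[i])
  }
  df$csx <- csx
  hs_rewrap(df, core, values = union(hs_values(core), "csx"))
}

#' Recursive allometric transformation of a cumulative series
#'
#' Applies the allometric model y = a * x^b to the cumulative series
#' \code{csx}, once per (a, b) pair in \code{mp}, in order. With
#' \code{mp = c(1, 1)} the radii are kept; \code{c(2, 1)} produces diameters;
#' \code{c(0.25 * pi, 2)} basal areas. Longer vectors chain transformations,
#' e.g. \code{c(2, 1, 2.87, 0.85)} converts radii to diameters inside bark
#' and then to diameters over bark. Increments are recomputed by differencing
#' the transformed cumulative series (first increment = first value), so
#' relative and cumulative growth stay on the same scale.
#'
#' @param core a \code{hier_series} for one series with a \code{csx} column.
#' @param mp flat numeric vector (a1, b1, ..., an, bn) of positive parameters.
#' @param to_cm logical; divide the input (mm) by 10 before transforming.
#' @return The core with \code{csx} and the increment column transformed.
#' @export
amod <- function(core, mp = c(1, 1), to_cm = FALSE) {
  if (length(mp) %% 2L != 0L || length(mp) < 2L)
    stop("allometric parameters must come in (a, b) pairs", call. = FALSE)
  if (any(!is.finite(mp)))
    stop("allometric parameters must be finite", call. = FALSE)
  df <- as.data.frame(core)
  df <- df[order(df$year), , drop = FALSE]
  y <- df$csx
  if (is.null(y)) stop("amod needs a csx column (run scacum first)", call. = FALSE)
  if (isTRUE(to_cm)) y <- y / 10
  for (i in seq_len(length(mp) / 2L)) {
    a <- mp[2L * i - 1L]; b <- mp[2L * i]
    if (b != 1 && any(y <= 0))
      stop("non-positive cumulative value under exponent ", b, call. = FALSE)
    y <- a * y^b
  }
  df$csx <- y
  df[[hs_values(core)[1L]]] <- c(y[1L], diff(y))
  hs_rewrap(df, core)
}

month_index <- function(m) {
  if (is.character(m)) {
    i <- match(m, month.abb)
    if (is.na(i)) i <- match(m, month.name)
    if (is.na(i)) stop("unknown month '", m, "'", call. = FALSE)
    return(i)
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m > 12 ||
      m != round(m))
    stop("initial month must be a month name or an integer in 1..12",
         call. = FALSE)
  as.integer(m)
}

#' Relabel monthly climate records by seasonal year
#'
#' Seasonal (e.g. meteorological) years can begin in a month other than
#' January. With \code{ini_mnt = "Oct"} the seasonal year labeled y runs from
#' October of calendar year y-1 through September of y, so records with month
#' >= October get their year label incremented. Records are re-ordered within
#' each seasonal year starting at \code{ini_mnt}, and incomplete seasonal
#' years (fewer than 12 months) at the edges of the record are dropped.
#'
#' @param climate a \code{hier_series} with a \code{month} time column.
#' @param ini_mnt first month of the seasonal year: English month name,
#'   abbreviation, or integer 1..12 (default "Oct").
#' @return The relabeled, reordered \code{hier_series}.
#' @export
move_yr <- function(climate, ini_mnt = "Oct") {
  if (!"month" %in% names(climate))
    stop("move_yr needs a month column", call. = FALSE)
  m0 <- month_index(ini_mnt)
  df <- as.data.frame(climate)
  if (m0 > 1L) df$year <- df$year + as.integer(df$month >= m0)
  df$mseq <- ((df$month - m0) %% 12L) + 1L   # position within the seasonal year
  grp <- do.call(paste, c(df[c(hs_factors(climate), "year")], sep = "\r"))
  full <- names(which(table(grp) == 12L))
  df <- df[grp %in% full, , drop = FALSE]
  ord <- do.call(order, c(rev(df[hs_factors(climate)]),
                          list(df$year, df$mseq)))
  df <- df[ord, , drop = FALSE]
  hs_rewrap(df, climate, values = union(hs_values(climate), "mseq"))
}

## ---- routine registry ------------------------------------------------------

.routines <- new.env(parent = emptyenv())

#' Register a one-level routine by name
#'
#' Routines receive an evaluation group (a \code{hier_series} subset) as first
#' argument plus any arguments of matching names, and return the processed
#' group. User routines registered here can join the \code{fns} chain of
#' \code{\link{recursive_eval}} and \code{\link{model_frame}}.
#'
#' @param name routine name used in \code{fns}.
#' @param fn function(group, ...).
#' @export
register_routine <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .routines)
  invisible(name)
}

get_routine <- function(name) {
  if (!exists(name, envir = .routines, inherits = FALSE))
    stop("unknown routine '", name, "'", call. = FALSE)
  get(name, envir = .routines, inherits = FALSE)
}

## match a per-group argument vector against a group's code path:
## longest dot-joined prefix (outermost first) whose name matches wins.
match_group_arg <- function(arg, path_outer_first) {
  if (is.null(names(arg))) return(arg)   # scalars/whole vectors broadcast
  for (k in rev(seq_along(path_outer_first))) {
    code <- paste(path_outer_first[seq_len(k)], collapse = ".")
    if (code %in% names(arg)) return(unname(arg[[code]]))
  }
  stop("argument names (", paste(names(arg), collapse = ", "),
       ") do not cover group '",
       paste(path_outer_first, collapse = "."), "'", call. = FALSE)
}

#' Apply a chain of one-level routines group by group
#'
#' Each routine in \code{fns} is evaluated independently within every level
#' of its matching entry in \code{lvs}. A factor-column level means the
#' routine runs once per combination of that factor and all coarser factors
#' (e.g. \code{lv = "sample"} runs once per core); a time-column level (e.g.
#' \code{"year"}) means the routine runs once per whole factor-group series
#' and handles the time dimension internally. Named vector arguments in
#' \code{more_args} are matched to groups by dot-joined code (outermost
#' first; shorter prefixes such as tree codes also match); unnamed vectors
#' and scalars are passed to every group unchanged.
#'
#' @param data a \code{hier_series}.
#' @param fns character vector of registered routine names, applied in order.
#' @param lvs matching vector of evaluation levels (factor or time columns).
#' @param more_args named list of routine arguments (vectors allowed).
#' @param ... scalar routine arguments, passed to every group.
#' @return The processed \code{hier_series}.
#' @export
recursive_eval <- function(data, fns = character(), lvs = character(),
                           more_args = list(), ...) {
  fns <- unlist(fns); lvs <- unlist(lvs)
  if (length(fns) != length(lvs))
    stop("fns and lvs must have the same length", call. = FALSE)
  if (length(fns) == 0L) return(data)
  extra <- list(...)
  if (length(extra)) more_args <- utils::modifyList(more_args, extra)
  for (i in seq_along(fns)) {
    fn <- get_routine(fns[i])
    data <- eval_one_level(data, fn, lvs[i], more_args)
  }
  data
}

eval_one_level <- function(data, fn, lv, more_args) {
  fcts <- hs_factors(data)
  if (lv %in% fcts) {
    gcols <- fcts[seq(match(lv, fcts), length(fcts))]
  } else if (lv %in% hs_times(data)) {
    gcols <- fcts                       # whole series per factor path
  } else stop("evaluation level '", lv, "' is not a column of the series",
              call. = FALSE)
  key <- interaction(data[rev(gcols)], drop = TRUE, sep = ".", lex.order = TRUE)
  idx <- split(seq_len(nrow(data)), key)
  take <- intersect(names(more_args), names(formals(fn)))
  pieces <- lapply(names(idx), function(code) {
    grp <- hs_rewrap(as.data.frame(data)[idx[[code]], , drop = FALSE], data)
    path <- strsplit(code, ".", fixed = TRUE)[[1L]]
    args <- lapply(more_args[take], match_group_arg, path_outer_first = path)
    as.data.frame(do.call(fn, c(list(grp), args)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  times <- intersect(hs_times(data), names(out))
  values <- setdiff(names(out), c(times, fcts))
  ## seasonal month position (mseq), when present, overrides calendar month order
  tord <- if ("mseq" %in% names(out)) {
    list(out[["year"]], out[["mseq"]])
  } else unname(out[rev(times)])
  ord <- do.call(order, c(rev(out[fcts]), tord))
  hier_series(out[ord, , drop = FALSE], values = values, times = times,
              factors = fcts)
}
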