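## Multilevel dendroclimatic data series (MDDS): canonical long tables of
## observations ordered by time units and nested ecological factors
## (e.g. core within tree within plot).

#' Construct a multilevel dendroclimatic data series
#'
#' A \code{hier_series} is a plain \code{data.frame} in canonical long form:
#' value column(s) first, then time columns (lower time units first, e.g.
#' \code{month} before \code{year}), then categorical factor columns ordered
#' innermost to outermost (e.g. \code{sample}, \code{tree}, \code{plot}).
#' Factor levels are kept as character strings: codes such as tree \code{"17"}
#' are labels, not numbers.
#'
#' @param records data.frame holding all columns.
#' @param values character vector of measurement column names.
#' @param times character vector of time column names, lower units first.
#' @param factors character vector of factor column names, innermost first.
#' @return A \code{hier_series} data.frame with attributes \code{values},
#'   \code{times} and \code{factors}.
#' @export
hier_series <- function(records, values, times, factors) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in c(values, times, factors))
    if (!nm %in% names(records))
      stop("column '", nm, "' not found in records", call. = FALSE)
  for (nm in factors)
    records[[nm]] <- as.character(records[[nm]])
  if ("year" %in% times) {
    yr <- records[["year"]]
    if (!is.numeric(yr) || any(yr != round(yr)))
      stop("years must be integers", call. = FALSE)
    records[["year"]] <- as.integer(round(yr))
  }
  if ("month" %in% times) {
    mo <- records[["month"]]
    if (!is.numeric(mo) || any(mo != round(mo)) || any(mo < 1L | mo > 12L))
      stop("months must be integers in 1..12", call. = FALSE)
    records[["month"]] <- as.integer(round(mo))
  }
  key <- do.call(paste, c(records[c(factors, times)], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (factors, time) keys in series", call. = FALSE)
  records <- records[c(values, times, factors)]
  rownames(records) <- NULL
  structure(records, values = values, times = times, factors = factors,
            class = c("hier_series", "data.frame"))
}

#' @export
print.hier_series <- function(x, ...) {
  cat("Multilevel series: ", nrow(x), " records; factors (inner->outer): ",
      paste(attr(x, "factors"), collapse = " < "), "\n", sep = "")
  NextMethod()
}

hs_values <- function(x) attr(x, "values")
hs_times <- function(x) attr(x, "times")
hs_factors <- function(x) attr(x, "factors")

## rebuild a hier_series from a modified data.frame, keeping metadata
hs_rewrap <- function(df, template, values = hs_values(template),
                      times = hs_times(template)) {
  hier_series(df, values = values, times = times,
              factors = hs_factors(template))
}

## ---- hierarchy codes -------------------------------------------------------

split_codes <- function(headers) strsplit(headers, ".", fixed = TRUE)

#' Render a hierarchy code from its level labels
#'
#' Codes are dot-joined, outermost level first (\code{"P16106.17.a"} =
#' plot.tree.core). Rendering then re-parsing is the identity.
#'
#' @param levels character vector of labels, outermost first; tokens must be
#'   non-empty and contain no dots.
#' @return A single dot-joined string.
#' @export
render_code <- function(levels) {
  levels <- as.character(levels)
  if (length(levels) == 0L || any(!nzchar(levels)) || any(grepl(".", levels, fixed = TRUE)))
    stop("code levels must be non-empty tokens without dots", call. = FALSE)
  paste(levels, collapse = ".")
}

#' Parse a dot-joined hierarchy code into its level labels
#' @param code a single dot-joined string.
#' @return Character vector of labels, outermost first.
#' @export
parse_code <- function(code) {
  parts <- split_codes(code)[[1L]]
  if (any(!nzchar(parts)))
    stop("malformed code '", code, "': empty level token", call. = FALSE)
  parts
}

default_level_names <- function(n) {
  switch(as.character(n),
         "1" = "plot",
         "2" = c("plot", "tree"),
         "3" = c("plot", "tree", "sample"),
         paste0("level", seq_len(n)))
}

## ---- wide growth tables ----------------------------------------------------

wide_years <- function(x) {
  labs <- rownames(x)
  yr <- suppressWarnings(as.numeric(labs))
  if (anyNA(yr) || any(yr != round(yr)))
    stop("row labels of wide tables must be integer years", call. = FALSE)
  as.integer(round(yr))
}

#' Parse a wide growth table into a multilevel series
#'
#' Wide growth tables are year-by-series matrices: rows labeled by calendar
#' year (earliest first), columns named with dot-joined hierarchy codes such
#' as \code{"P16106.17.a"} (plot.tree.core) holding ring widths in mm. Blank
#' cells are missing and are dropped from the long output.
#'
#' @param x data.frame or matrix with year row labels and coded columns.
#' @param level_names labels for the code fields, outermost first; defaults to
#'   \code{c("plot","tree","sample")} for three-field codes.
#' @param value name of the measurement column in the output (default "x").
#' @return A \code{hier_series} with one record per non-missing cell.
#' @export
parse_wide_growth <- function(x, level_names = NULL, value = "x") {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("wide table has no series columns", call. = FALSE)
  headers <- names(x)
  if (anyDuplicated(headers))
    stop("duplicate series headers: ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "),
         call. = FALSE)
  parts <- split_codes(headers)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L)
    stop("inconsistent dot-field counts across headers (e.g. '",
         headers[which.min(nf)], "' vs '", headers[which.max(nf)], "')",
         call. = FALSE)
  nf <- nf[1L]
  if (is.null(level_names)) level_names <- default_level_names(nf)
  if (length(level_names) != nf)
    stop("headers have ", nf, " fields but ", length(level_names),
         " level names were given", call. = FALSE)
  years <- wide_years(x)
  recs <- lapply(seq_along(headers), function(j) {
    v <- x[[j]]
    keep <- !is.na(v)
    if (!any(keep)) return(NULL)
    out <- data.frame(v = v[keep], year = years[keep],
                      stringsAsFactors = FALSE)
    for (k in rev(seq_len(nf)))           # innermost factor first
      out[[level_names[k]]] <- parts[[j]][k]
    out
  })
  long <- do.call(rbind, recs)
  if (is.null(long)) stop("wide table holds no non-missing cells", call. = FALSE)
  names(long)[1L] <- value
  hier_series(long, values = value, times = "year",
              factors = rev(level_names))
}

#' Reshape a multilevel growth series back to its wide table
#'
#' Inverse of \code{\link{parse_wide_growth}} up to column order: one column
#' per factor path, rows labeled by year, missing years blank.
#'
#' @param hs a \code{hier_series} with a single value column and yearly time.
#' @return data.frame with year rownames and dot-coded columns.
#' @export
as_wide_growth <- function(hs) {
  fcts <- hs_factors(hs)
  val <- hs_values(hs)[1L]
  code <- do.call(paste, c(rev(hs[fcts]), sep = "."))   # outermost first
  years <- sort(unique(hs$year))
  cols <- sort(unique(code))
  wide <- matrix(NA_real_, length(years), length(cols),
                 dimnames = list(years, cols))
  wide[cbind(match(hs$year, years), match(code, cols))] <- hs[[val]]
  as.data.frame(wide, check.names = FALSE)
}

## ---- wide climate tables ---------------------------------------------------

month_number <- function(tok) {
  m <- match(tok, month.abb)
  if (anyNA(m))
    stop("unknown month token(s): ",
         paste(unique(tok[is.na(m)]), collapse = ", "), call. = FALSE)
  m
}

melt_climate <- function(x, value) {
  headers <- names(x)
  parts <- split_codes(headers)
  if (any(lengths(parts) != 2L))
    stop("climate headers must be 'plot.Mon' (got e.g. '",
         headers[which(lengths(parts) != 2L)[1L]], "')", call. = FALSE)
  plot <- vapply(parts, `[`, "", 1L)
  mon <- month_number(vapply(parts, `[`, "", 2L))
  years <- wide_years(x)
  long <- data.frame(
    v = unlist(x, use.names = FALSE),
    month = rep(mon, each = length(years)),
    year = rep(years, times = length(headers)),
    plot = rep(plot, each = length(years)),
    stringsAsFactors = FALSE)
  names(long)[1L] <- value
  long[!is.na(long[[value]]), ]
}

#' Parse paired wide climate tables into a long climate series
#'
#' Climate tables carry one column per \code{"plot.Mon"} combination
#' (\code{Mon} a three-letter English month abbreviation, e.g.
#' \code{"P16106.Apr"}), rows labeled by year: one table of monthly
#' cumulative precipitation (mm) and one of monthly mean temperature (deg C).
#' The two are joined on (plot, year, month).
#'
#' @param prec wide precipitation table.
#' @param temp wide temperature table.
#' @return A \code{hier_series} with columns \code{prec}, \code{temp},
#'   \code{month}, \code{year}, \code{plot}.
#' @export
parse_wide_climate <- function(prec, temp) {
  lp <- melt_climate(as.data.frame(prec), "prec")
  lt <- melt_climate(as.data.frame(temp), "temp")
  joined <- merge(lp, lt, by = c("plot", "year", "month"))
  if (nrow(joined) == 0L)
    stop("precipitation and temperature tables share no (plot, year) records",
         call. = FALSE)
  hier_series(joined[c("prec", "temp", "month", "year", "plot")],
              values = c("prec", "temp"), times = c("month", "year"),
              factors = "plot")
}

## ---- long tables -----------------------------------------------------------

#' Parse a long growth table into a canonical multilevel series
#'
#' Long tables list the measurement and time columns first, then factor
#' columns innermost to outermost (e.g. \code{x, year, sample, tree, plot}).
#'
#' @param tab data.frame in long form.
#' @param value_col measurement column name; default: first numeric column.
#' @param time_cols time column names, lower units first (default "year").
#' @param factor_cols factor column names innermost first; default: all
#'   remaining columns in table order.
#' @return A \code{hier_series}; duplicate (factors, time) keys are an error.
#' @export
parse_long_growth <- function(tab, value_col = NULL, time_cols = "year",
                              factor_cols = NULL) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (is.null(value_col)) {
    num <- names(tab)[vapply(tab, is.numeric, TRUE)]
    num <- setdiff(num, time_cols)
    if (length(num) == 0L) stop("no numeric measurement column found", call. = FALSE)
    value_col <- num[1L]
  }
  if (is.null(factor_cols))
    factor_cols <- setdiff(names(tab), c(value_col, time_cols))
  hier_series(tab, values = value_col, times = time_cols,
              factors = factor_cols)
}

## ---- CSV readers/writers ---------------------------------------------------

read_wide_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                       na.strings = c("NA", ""))
  x
}

#' Read a wide growth CSV (years in the first column) as a multilevel series
#' @param path CSV path; header row required, first column calendar years,
#'   remaining columns dot-coded series; empty cells are missing.
#' @inheritParams parse_wide_growth
#' @export
read_wide_growth <- function(path, level_names = NULL)
  parse_wide_growth(read_wide_table(path), level_names = level_names)

#' Read paired wide climate CSVs as a long climate series
#' @param prec_path,temp_path CSV paths in the wide climate dialect.
#' @export
read_wide_climate <- function(prec_path, temp_path)
  parse_wide_climate(read_wide_table(prec_path), read_wide_table(temp_path))

#' Read a long growth CSV as a multilevel series
#' @param path CSV path in long form.
#' @inheritParams parse_long_growth
#' @export
read_long_growth <- function(path, value_col = NULL, time_cols = "year",
                             factor_cols = NULL)
  parse_long_growth(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE,
                                    colClasses = NA,
                                    na.strings = c("NA", "")),
                    value_col = value_col, time_cols = time_cols,
                    factor_cols = factor_cols)

#' Write a multilevel series to canonical long CSV
#' @param hs a \code{hier_series}.
#' @param path output CSV path.
#' @export
write_hier_series <- function(hs, path)
  utils::write.csv(as.data.frame(hs), path, row.names = FALSE, na = "")

#' Read a named vector of reference tree radii
#'
#' The CSV must carry columns \code{code} (dot-joined plot.tree codes) and
#' \code{radius} (mm, strictly positive); the common measurement year is
#' passed separately to the pipeline (argument \code{rf_t}).
#'
#' @param path CSV path.
#' @return Named numeric vector of radii.
#' @export
read_radii <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "radius") %in% names(tab)))
    stop("radii CSV needs columns 'code' and 'radius'", call. = FALSE)
  radii(stats::setNames(tab$radius, tab$code))
}

#' Validate a named radius vector
#' @param x named numeric vector, names are tree-level codes (plot.tree),
#'   values strictly positive radii in mm.
#' @export
radii <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("radii must be named with tree codes", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("one radius entry per tree code", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("radii must be strictly positive", call. = FALSE)
  x
}
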