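## Mantel correlograms between two sets of detrended fluctuations sharing an
## outermost factor: one matrix supplies standardized distances (z), the
## other defines binary distance-class membership (w); r(d) is the mean z
## within class d, tested by permuting the z matrix rows and columns.

#' Sturges class count for a Mantel correlogram
#'
#' Number of distance classes d = ceiling(1 + 3.3 log10(m)), with m the
#' number of pairwise distances in the upper triangle.
#'
#' @param m pair count, >= 1.
#' @return Integer class count.
#' @export
sturges_nclass <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("pair count must be >= 1", call. = FALSE)
  as.integer(ceiling(1 + 3.3 * log10(m)))
}

#' Standardized Euclidean distance matrix of one series
#'
#' All pairwise absolute differences |x_i - x_j|, standardized to z-scores
#' over the upper triangle (mean 0, sample SD 1).
#'
#' @param x numeric series (>= 3 values, not constant), optionally named by
#'   year.
#' @return Symmetric matrix of standardized distances, diagonal NA.
#' @export
standardized_dists <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("at least 3 observations are required", call. = FALSE)
  d <- abs(outer(x, x, "-"))
  ut <- upper.tri(d)
  s <- stats::sd(d[ut])
  if (!is.finite(s) || s == 0)
    stop("constant series: distances have zero standard deviation",
         call. = FALSE)
  z <- (d - mean(d[ut])) / s
  diag(z) <- NA_real_
  z
}

#' Equal-width distance classes from a distance matrix
#'
#' Bins the upper-triangle distances into \code{nclass} equal-width classes
#' over their observed range (count from the Sturges rule when NULL). Every
#' pair falls in exactly one class.
#'
#' @param dmat symmetric distance matrix (e.g. from
#'   \code{\link{standardized_dists}}).
#' @param nclass class count; NULL applies \code{\link{sturges_nclass}} to
#'   the pair count.
#' @return Object of class \code{dist_classes}: integer class matrix,
#'   midpoints, per-class pair counts.
#' @export
distance_classes <- function(dmat, nclass = NULL) {
  ut <- upper.tri(dmat)
  m <- sum(ut)
  nclass <- nclass %||% sturges_nclass(m)
  rng <- range(dmat[ut])
  breaks <- seq(rng[1L], rng[2L], length.out = nclass + 1L)
  cls <- matrix(NA_integer_, nrow(dmat), ncol(dmat))
  idx <- findInterval(dmat[ut | t(ut)], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cls[ut | t(ut)] <- idx
  structure(list(class = cls, nclass = nclass,
                 midpoints = (breaks[-1L] + breaks[-(nclass + 1L)]) / 2,
                 n_pairs = tabulate(cls[ut], nbins = nclass)),
            class = "dist_classes")
}

#' Mantel statistic per distance class
#'
#' Evaluates sum_ij w_ij z_ij / sum_ij w_ij over the upper triangle, with
#' w_ij the binary membership of pair (i, j) in class d — the mean
#' standardized distance within the class — and reports it with the
#' correlogram sign convention (negated), so that pairs more similar than
#' average within a class give a positive r: positive association at short
#' distances reads as positive r, as in the mainstream Mantel-correlogram
#' implementations. Empty classes give NA.
#'
#' @param z standardized distance matrix.
#' @param classes a \code{dist_classes} object on the same observations.
#' @return Numeric vector r of length \code{classes$nclass}.
#' @export
mantel_r <- function(z, classes) {
  ut <- upper.tri(z)
  vapply(seq_len(classes$nclass), function(d) {
    w <- ut & !is.na(classes$class) & classes$class == d
    if (!any(w)) return(NA_real_)
    -mean(z[w])
  }, numeric(1))
}

#' Permutation test of per-class Mantel statistics
#'
#' Permutes the rows and columns of the z matrix simultaneously
#' \code{nperm} times and compares |r| per class against the observed
#' value; two-sided p = (1 + #{|r_perm| >= |r_obs|}) / (nperm + 1).
#'
#' @inheritParams mantel_r
#' @param nperm number of permutations (>= 1).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of p-values per class (NA for empty classes).
#' @export
mantel_perm <- function(z, classes, nperm = 999L, seed = NULL) {
  stopifnot(nperm >= 1L)
  robs <- mantel_r(z, classes)
  n <- nrow(z)
  ut <- upper.tri(z)
  masks <- lapply(seq_len(classes$nclass), function(d)
    ut & !is.na(classes$class) & classes$class == d)
  counts <- numeric(classes$nclass)
  with_seed(seed, {
    for (i in seq_len(nperm)) {
      idx <- sample.int(n)
      zp <- z[idx, idx]
      for (d in seq_len(classes$nclass)) {
        if (is.na(robs[d])) next
        rp <- -mean(zp[masks[[d]]])
        if (abs(rp) >= abs(robs[d])) counts[d] <- counts[d] + 1
      }
    }
  })
  p <- (1 + counts) / (nperm + 1)
  p[is.na(robs)] <- NA_real_
  p
}

#' Mantel correlogram between one growth series and one climate series
#'
#' Pairs the two series on their common years, standardizes both distance
#' matrices, takes z from the growth distances and the distance classes
#' from the climate distances, and runs the per-class permutation test.
#'
#' @param x growth fluctuation values, named by year.
#' @param y climate fluctuation values, named by year.
#' @inheritParams mantel_perm
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame(class, midpoint, r, p, n_pairs, significant).
#' @export
mantel_correlog <- function(x, y, nperm = 999L, seed = NULL, alpha = 0.05) {
  yrs <- intersect(names(x), names(y))
  if (length(yrs) < 3L)
    stop("fewer than 3 common years between the two series", call. = FALSE)
  z <- standardized_dists(x[yrs])
  dc <- standardized_dists(y[yrs])
  classes <- distance_classes(dc)
  r <- mantel_r(z, classes)
  p <- mantel_perm(z, classes, nperm = nperm, seed = seed)
  data.frame(class = seq_len(classes$nclass),
             midpoint = classes$midpoints,
             r = r, p = p, n_pairs = classes$n_pairs,
             significant = !is.na(p) & p <= alpha)
}

#' Multivariate comparison of two model frames
#'
#' For every innermost series of the growth frame (each core), pairs its
#' fluctuations with the fluctuation series of its plot (the shared
#' outermost factor) in the climate frame, restricted to common years, and
#' computes a Mantel correlogram with permutation p-values per distance
#' class: growth distances supply z, climate distances define the classes.
#'
#' @param growth_frame a growth \code{model_frame}.
#' @param cd a climate/aridity \code{model_frame} sharing the outermost
#'   factor with \code{growth_frame}.
#' @param nperm permutations per series (default 1000).
#' @param seed optional integer seed; series get reproducible sub-seeds.
#' @param alpha significance level for the \code{significant} flag.
#' @param res_type residual type of the compared fluctuations.
#' @return data.frame(series, class, midpoint, r, p, n_pairs, significant),
#'   one block of rows per core.
#' @export
mule_man <- function(growth_frame, cd, nperm = 1000L, seed = NULL,
                     alpha = 0.05, res_type = "raw") {
  gf <- fluctuations(growth_frame, res_type = res_type)
  cf <- fluctuations(cd, res_type = res_type)
  gfac <- hs_factors(gf); cfac <- hs_factors(cf)
  outer_g <- gfac[length(gfac)]; outer_c <- cfac[length(cfac)]
  shared <- intersect(unique(gf[[outer_g]]), unique(cf[[outer_c]]))
  if (length(shared) == 0L)
    stop("the two frames share no outermost-factor level", call. = FALSE)
  code <- do.call(paste, c(rev(as.data.frame(gf)[gfac]), sep = "."))
  pieces <- list()
  series <- unique(code[gf[[outer_g]] %in% shared])
  for (i in seq_along(series)) {
    sc <- series[i]
    sub <- as.data.frame(gf)[code == sc, , drop = FALSE]
    plt <- sub[[outer_g]][1L]
    csub <- as.data.frame(cf)[cf[[outer_c]] == plt, , drop = FALSE]
    x <- stats::setNames(sub$fluc, sub$year)
    y <- stats::setNames(csub$fluc, csub$year)
    sub_seed <- if (is.null(seed)) NULL else seed + i - 1L
    mc <- mantel_correlog(x, y, nperm = nperm, seed = sub_seed,
                          alpha = alpha)
    pieces[[i]] <- cbind(series = sc, mc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
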