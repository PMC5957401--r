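## fixture builders shared across the test files; everything is generated in
## code, nothing is read from disk

## tiny wide growth table: 2 plots x 2 trees x 2 cores, 5 years, no gaps
tiny_wide_growth <- function(years = 1990:1994) {
  codes <- c(t(outer(c("PA", "PB"), c("1.a", "1.b", "2.a", "2.b"),
                     paste, sep = ".")))
  set.seed(99)
  x <- matrix(round(runif(length(years) * length(codes), 0.2, 2), 3),
              nrow = length(years), dimnames = list(years, codes))
  as.data.frame(x)
}

## one plot's wide climate tables over full calendar years
tiny_wide_climate <- function(years = 1999:2001, plots = "PA",
                              prec_fun = function(m) 40 + 30 * cos(2 * pi * (m - 1) / 12),
                              temp_fun = function(m) 12 + 8 * cos(2 * pi * (m - 7) / 12)) {
  cols_p <- list(); cols_t <- list()
  for (p in plots) for (m in 1:12) {
    cols_p[[paste(p, month.abb[m], sep = ".")]] <- rep(prec_fun(m), length(years))
    cols_t[[paste(p, month.abb[m], sep = ".")]] <- rep(temp_fun(m), length(years))
  }
  prec <- as.data.frame(cols_p, check.names = FALSE)
  temp <- as.data.frame(cols_t, check.names = FALSE)
  rownames(prec) <- rownames(temp) <- years
  list(prec = prec, temp = temp)
}

## a long series for one tree with two cores of staggered year spans
staggered_tree <- function() {
  hier_series(data.frame(
    x = c(1, 2, 3, 4, 5, 10, 20, 30),
    year = c(1990:1994, 1992:1994),
    sample = c(rep("a", 5), rep("b", 3)),
    tree = "17", plot = "P1", stringsAsFactors = FALSE),
    values = "x", times = "year", factors = c("sample", "tree", "plot"))
}

## quiet model_frame: silences optimizer chatter, keeps results
fit_quiet <- function(expr) suppressWarnings(suppressMessages(expr))

## independent high-resolution aridity oracle: plain fine-grid trapezoid
## integration of the month-midpoint polylines, no node/crossing refinement
wlai_oracle <- function(prec, temp, npts = 1e4, sqt = FALSE) {
  edge_p <- (prec[12] + prec[1]) / 2
  edge_e <- (2 * temp[12] + 2 * temp[1]) / 2
  nx <- c(0, 1:12 - 0.5, 12)
  xs <- seq(0, 12, length.out = npts)
  P <- approx(nx, c(edge_p, prec, edge_p), xout = xs)$y
  E <- approx(nx, c(edge_e, 2 * temp, edge_e), xout = xs)$y
  tr <- function(y) sum(diff(xs) * (y[-1] + y[-length(y)]) / 2)
  ai <- tr(pmax(E - P, 0)) / tr(pmax(P - E, 0))
  if (sqt) sqrt(ai) else ai
}

## direct dense-matrix REML log-likelihood (Harville), the oracle for the
## profiled likelihood returned by the fitter
reml_loglik_oneway <- function(y, grp, sigma_b, sigma_w) {
  X <- matrix(1, length(y), 1)
  Z <- stats::model.matrix(~ grp - 1)
  V <- sigma_b^2 * Z %*% t(Z) + sigma_w^2 * diag(length(y))
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% bhat
  as.numeric(-0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
                     determinant(V)$modulus +
                     determinant(t(X) %*% Vi %*% X)$modulus +
                     t(r) %*% Vi %*% r))
}
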