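test_that("rtimes pools relative time over the group and filters singletons", {
  tr <- staggered_tree()                  # core a 1990-94, core b 1992-94
  out <- rtimes(tr, only_dup = FALSE)
  expect_equal(out$time[out$sample == "a"], 1:5)
  expect_equal(out$time[out$sample == "b"], 3:5)

  dup <- rtimes(tr, only_dup = TRUE)
  expect_equal(nrow(dup), 6L)             # times 3,4,5 in both cores
  expect_equal(sort(unique(dup$time)), 3:5)
  expect_true(all(table(dup$time) == 2L))

  single <- hier_series(as.data.frame(tr)[tr$sample == "a", ],
                        values = "x", times = "year",
                        factors = c("sample", "tree", "plot"))
  kept <- rtimes(single, only_dup = TRUE) # all times unique: filter ignored
  expect_equal(kept$time, 1:5)

  same <- hier_series(data.frame(x = 1:6, year = rep(1990:1992, 2),
                                 sample = rep(c("a", "b"), each = 3),
                                 tree = "1", plot = "P",
                                 stringsAsFactors = FALSE),
                      values = "x", times = "year",
                      factors = c("sample", "tree", "plot"))
  expect_equal(nrow(rtimes(same, only_dup = TRUE)), 6L)  # nothing removed
})

test_that("scacum cumulates and additively rescales to a reference radius", {
  core <- hier_series(data.frame(x = c(1, 2, 3), year = 2001:2003,
                                 sample = "a", tree = "1", plot = "P",
                                 stringsAsFactors = FALSE),
                      values = "x", times = "year",
                      factors = c("sample", "tree", "plot"))
  expect_equal(scacum(core)$csx, c(1, 3, 6))

  sc <- scacum(core, sc_c = 10, rf_t = 2003)
  expect_equal(sc$csx, c(5, 7, 10))
  expect_equal(diff(sc$csx), sc$x[-1])    # offset preserves increments

  expect_equal(scacum(core, sc_c = 10)$csx, c(5, 7, 10))  # rf_t defaults last
  expect_error(scacum(core, sc_c = 10, rf_t = 1990), "outside")
  expect_error(scacum(core, sc_c = -2), "positive")
})

test_that("amod applies the allometric recursion and rebuilds increments", {
  core <- scacum(hier_series(
    data.frame(x = c(2, 3), year = 2001:2002, sample = "a", tree = "1",
               plot = "P", stringsAsFactors = FALSE),
    values = "x", times = "year", factors = c("sample", "tree", "plot")))

  ident <- amod(core, mp = c(1, 1))
  expect_equal(ident$csx, core$csx)
  expect_equal(ident$x, core$x)

  diam <- amod(core, mp = c(2, 1))
  expect_equal(diam$csx, 2 * core$csx)

  ba <- amod(core, mp = c(0.25 * pi, 2))
  expect_equal(ba$csx, 0.25 * pi * core$csx^2)
  expect_equal(ba$csx[core$csx == 2], pi)

  ## radius (mm) -> dib (cm) -> dbh over bark: 2.87 * (2*50)^0.85
  big <- hier_series(data.frame(x = 500, year = 2001, sample = "a",
                                tree = "1", plot = "P",
                                stringsAsFactors = FALSE),
                     values = "x", times = "year",
                     factors = c("sample", "tree", "plot"))
  dbh <- amod(scacum(big), mp = c(2, 1, 2.87, 0.85), to_cm = TRUE)
  expect_equal(dbh$csx, 2.87 * 100^0.85, tolerance = 1e-10)
  expect_equal(round(dbh$csx, 2), 143.84)

  expect_error(amod(core, mp = c(1, 1, 2)), "pairs")
  neg <- core; neg$csx <- c(-1, 2)
  expect_error(amod(neg, mp = c(1, 0.5)), "non-positive")
})

test_that("move_yr relabels seasonal years and drops incomplete ones", {
  cl <- parse_wide_climate(tiny_wide_climate(1949:1951)$prec,
                           tiny_wide_climate(1949:1951)$temp)
  mv <- move_yr(cl, ini_mnt = "Oct")
  oct <- mv[mv$month == 10L, ]
  sep <- mv[mv$month == 9L, ]
  expect_true(all(oct$year == c(1950, 1951)))  # Oct 1949 -> seasonal 1950
  expect_true(all(sep$year == c(1950, 1951)))  # Sep 1950 -> seasonal 1950
  ## edges: seasonal 1949 (no Oct-Dec 1948) and 1952 (no Jan-Sep 1952) gone
  expect_equal(sort(unique(mv$year)), c(1950L, 1951L))
  expect_true(all(table(mv$year) == 12L))
  ## within a seasonal year the months run Oct..Sep
  expect_equal(mv$month[mv$year == 1950], c(10:12, 1:9))

  jan <- move_yr(cl, ini_mnt = "Jan")
  expect_equal(sort(unique(jan$year)), 1949:1951)
  expect_equal(nrow(jan), nrow(cl))       # identity configuration
  expect_error(move_yr(cl, ini_mnt = "Movember"), "unknown month")
  expect_error(move_yr(cl, ini_mnt = 13), "1..12")
})

test_that("recursive_eval vectorizes routines over their levels", {
  w <- tiny_wide_growth()
  hs <- parse_wide_growth(w)
  out <- recursive_eval(hs, fns = c("rtimes", "scacum", "amod"),
                        lvs = c("tree", "sample", "sample"))
  expect_true(all(c("time", "csx") %in% names(out)))
  ## per-core cumulative sums restart at each core
  one <- out[out$plot == "PA" & out$tree == "1" & out$sample == "a", ]
  expect_equal(one$csx, cumsum(one$x))

  expect_identical(recursive_eval(hs), hs)                 # no-op
  expect_error(recursive_eval(hs, fns = c("rtimes"), lvs = c("tree", "sample")),
               "same length")
  expect_error(recursive_eval(hs, fns = "nope", lvs = "tree"), "unknown routine")
})

test_that("named vector arguments are matched to groups by code prefix", {
  w <- tiny_wide_growth()
  hs <- parse_wide_growth(w)
  rads <- c(PA.1 = 50, PA.2 = 60, PB.1 = 70, PB.2 = 80)
  out <- recursive_eval(hs, fns = c("rtimes", "scacum"),
                        lvs = c("tree", "sample"),
                        more_args = list(sc_c = rads, rf_t = 1994))
  ## every core ends at its tree's radius in 1994
  last <- out[out$year == 1994, ]
  expect_equal(last$csx,
               unname(rads[paste(last$plot, last$tree, sep = ".")]))

  expect_error(recursive_eval(hs, fns = c("rtimes", "scacum"),
                              lvs = c("tree", "sample"),
                              more_args = list(sc_c = c(PA.1 = 50))),
               "do not cover")
})

test_that("user routines can be registered and chained", {
  register_routine("halve", function(group) {
    df <- as.data.frame(group)
    df[[1L]] <- df[[1L]] / 2
    hier_series(df, values = attr(group, "values"),
                times = attr(group, "times"),
                factors = attr(group, "factors"))
  })
  hs <- parse_wide_growth(tiny_wide_growth())
  out <- recursive_eval(hs, fns = "halve", lvs = "sample")
  expect_equal(sort(out$x), sort(hs$x / 2))
})
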