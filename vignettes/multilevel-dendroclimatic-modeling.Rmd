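---
title: "Multilevel modeling and comparison of dendroclimatic fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel modeling and comparison of dendroclimatic fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroflux)
```

## The problem

Tree-ring width (TRW) series sampled in forest stands are hierarchical:
several increment cores are taken per tree, several trees per plot, and the
plots sit in contrasting climate regimes. Conventional dendroclimatic
detrending works one series at a time and treats this sampling structure as
noise. `dendroflux` instead models the whole multilevel data set at once: it
synchronizes and cumulates the ring widths, removes the ontogenetic growth
trend with a mixed-effects model whose random effects follow the sampling
hierarchy, summarizes drought with an annual aridity index derived from
Walter-Lieth diagrams, and compares the two sets of detrended fluctuations
with Mantel correlograms.

## Data model

All modules operate on one canonical long table (`hier_series`): measurement
columns first, then time columns (lower units first, month before year),
then categorical factors ordered innermost to outermost (core, tree, plot).
Wide inputs use dot-joined column codes (`"P16106.17.a"` is core `a` of tree
`17` in plot `P16106`; `"P16106.Apr"` is April of that plot), rows labeled by
calendar year. Factor codes stay character strings — tree `"17"` is a label.
Blank cells in wide tables are missing values and simply drop out of the
long form; the parsers reject ragged header field counts, duplicate headers,
non-integer year labels and duplicate (factors, time) keys.

## One-level routines

Processing steps are "one-level functions": each runs independently inside
every level of one factor, orchestrated by `recursive_eval()`.

* `rtimes` adds relative time `time = year - min(year) + 1`, computed from
  the pooled earliest year of the evaluation group (the tree). With
  `only_dup = TRUE`, years present in a single core are dropped, so the
  subsequent detrending only sees replicated times; when every time is
  unique (a single core) the filter is skipped. Measuring time from the
  pooled group minimum rather than per core (cambial age) is a deliberate
  choice: it makes "duplicated" mean "same calendar year in at least two
  cores", which is what synchronized replicates share.
* `scacum` forms the running sum `csx` of the ring widths, optionally
  rescaled to a measured tree radius. The rescaling is *additive*: the
  cumulative series is shifted so it equals the radius `sc_c` at the
  reference year `rf_t`. An additive offset preserves every increment
  exactly and has a physical reading — a core that misses its innermost
  rings is missing a constant inner radius. A multiplicative rescaling
  would distort the very ring widths being modeled.
* `amod` applies the allometric model y = a x^b to the cumulative series,
  once per parameter pair, and rebuilds the increments by differencing the
  transformed cumulative series, so relative and cumulative growth stay on
  one scale. `c(1, 1)` keeps radii, `c(2, 1)` gives diameters,
  `c(0.25*pi, 2)` basal areas, and chained pairs like `c(2, 1, 2.87, 0.85)`
  convert radii to over-bark diameters.
* `moveYr` relabels monthly climate records by seasonal year (default:
  years begin in October, the meteorological year in Spain), reorders
  months within the seasonal year and drops incomplete seasonal years at
  the record edges.
* `wlai` turns twelve monthly precipitation sums and mean temperatures into
  one annual aridity index (below).

Named vector arguments (such as a radius vector indexed by `plot.tree`
codes) are matched to evaluation groups by the longest dot-joined code
prefix; scalars and unnamed vectors are broadcast unchanged. The registry is
open: `register_routine()` lets user functions join the chain.

## The detrending model

The growth form is the log-linear balance equation

$$\ln x_t = \beta_0 + \beta_1 \ln(\mathrm{csx}_t) - \beta_2 f(t) + \epsilon_t$$

with $x$ the ring increment, csx the cumulative growth and $f(t)$ either
$t$ (time-decline, Chapman-Richards-like) or $\ln t$ (logarithmic
time-decline, Levakovic-like; `log_t = TRUE`). Each coefficient carries
nested random effects at every grouping level (plot, tree within plot, core
within tree), with either a diagonal covariance (`rand_diag`, one SD per
covariate per level, the default) or a multiple of the identity
(`rand_ident`). `lev_rm` removes levels from the grouping, down to plain
OLS when all are removed. Aridity fluctuations use the linear form
`AI ~ year` with the same machinery (`lme_form`).

Estimation is restricted maximum likelihood. The models are standard
Gaussian linear mixed models, so fitting is delegated to `nlme::lme` —
diagonal and identity random structures map to `pdDiag`/`pdIdent`, ARMA
within-group correlation to `corARMA`, and the constant-plus-power residual
variance $\mathrm{Var}(\epsilon) = \sigma^2(\varrho_1 + |\nu|^{\varrho_2})^2$
to `varConstPower`. The surrounding layer is ours and is what the tests pin
down: formula resolution, the OLS degenerate case (fitted exactly by least
squares, with the restricted log-likelihood so comparisons against REML
fits stay coherent), information criteria, likelihood-ratio and conditional
t-tests, residual whitening and pooled autocorrelation. The quasi-Newton
optimizer (`nlminb`) is tried first and an `optim`-based pass serves as
fallback on awkward likelihood surfaces.

Two conventions deserve a note. BIC is computed as
$-2\ell + k\,\ln(N - p)$ with $p$ the number of fixed-effect coefficients:
the restricted likelihood is a likelihood of $N - p$ linearly transformed
observations, and this effective-sample-size convention is what the
standard REML software reports. And REML likelihoods of models with
different fixed-effect structures are not strictly comparable;
`lr_test()` computes the requested statistic but warns when it detects
this situation.

Diagnostics: normalized residuals are obtained by forward-solving the lower
Cholesky factor of the estimated within-group covariance against the raw
residuals (`whiten_residuals` exposes the kernel); under a correct model
they are approximately white with unit variance. `acf_resid`/`acf_fluc`
pool the empirical autocorrelation across innermost groups,
$\hat\rho(l) = \frac{\sum_c \sum_t e_{c,t}e_{c,t-l}/N(l)}
{\sum_c \sum_t e_{c,t}^2/N(0)}$, with two-sided normal bounds
$\pm z_{1-\alpha/2}/\sqrt{N(l)}$. An ARMA(1,1) residual process — whose
theoretical autocorrelation `arma_corr` evaluates in closed form — decays
exponentially from lag 2 on and is usually enough to whiten TRW
fluctuations.

`model_frame()` ties everything together and stores three things: the
fitted model, the fluctuation table (by default the *raw* within-group
residuals, which is what detrended-series plots show; normalized residuals
are available via `res_type`), and the fully resolved call arguments.
Because the call record stores values rather than references,
`update_frame()` is deterministic: updating with no changes reproduces the
frame, and updating one argument changes only what it names.

## The annual aridity index

A Walter-Lieth diagram plots monthly precipitation P against the
evaporation equivalent E = 2T (1 degree C of monthly mean temperature
corresponds to 2 mm/month of evaporation). The annual aridity index is the
ratio of the dry area (E above P) to the wet area (P above E).

Construction: months sit at midpoints of unit intervals on [0, 12]; the
curves close at the year edges by linear continuation between the December
and January neighbors of the (already seasonally shifted) year. Both curves
are piecewise linear, so the areas are integrated *exactly*: the trapezoid
grid is augmented with the curve nodes and the P/E crossing points, which
makes the index invariant to grid resolution (the `npts` default of 365 is
a plotting convenience, not an accuracy knob). No >100 mm
precipitation-axis compression is applied — that is a plotting convention
of published diagrams, whereas the index is defined directly by the two
curves. A fully humid year gives 0; when the wet area is zero the index is
undefined and propagates as NA with a warning rather than aborting a
multi-plot run. The square-root transform (`sqt = TRUE`, the default) is
what makes the index series approximately stationary and weakly
autocorrelated, which is why a simple linear year trend suffices to detrend
it.

## Mantel correlograms

`mule_man()` compares the fluctuations of a growth frame and an aridity
frame that share their outermost factor: every core is paired with its
plot's aridity series on their common years. Distances are absolute
differences between years, standardized to z-scores over the pairs. The
climate distances are cut into equal-width classes — class count from the
Sturges rule $d = \lceil 1 + 3.3\log_{10} m\rceil$ with $m$ the number of
pairs — and the statistic per class is the mean standardized growth
distance among the pairs of that class, *negated*. The negation is the
standard correlogram sign convention (as in the mainstream Mantel
correlogram implementations): pairs of years whose aridity is similar and
whose growth fluctuations are also more similar than average yield a
positive r, so positive association at short climatic distance reads as
positive r. Significance per class comes from simultaneously permuting the
rows and columns of the z matrix, with the add-one two-sided estimate
$p = (1 + \#\{|r^\ast| \ge |r|\})/(n_\mathrm{perm} + 1)$, which can never
return 0. Class membership comes from the climate matrix and z from the
growth matrix; equal-width binning over the observed range is used because
it is the standard correlogram choice (equal-frequency classes are the main
alternative; they change midpoints, not the machinery).

## Synthetic data

`sim_design()`/`gen_growth()`/`gen_climate()` generate the fixtures all
tests run on. The growth generator draws nested random effects for all
three coefficients, then iterates the growth equation year by year *on the
log-increment scale with the contemporaneous cumulative sum*: each year's
increment solves $\ln x = \beta_0 + \beta_1\ln(\mathrm{csx}_{t-1} + x) -
\beta_2 f(t) + \epsilon$ (a fixed-point contraction for $\beta_1 < 1$; the
first year closes in closed form). The detrending pipeline therefore fits
exactly the data-generating equation, which makes parameter recovery a
well-posed experiment. Residuals can follow an ARMA process. Ring widths
are strictly positive by construction.

Defaults emulate the published sampling design: 2 plots x 2 trees x 2
cores over 125 years (~1000 rings), with coefficients (-0.8, 0.5, -0.02)
and level SDs chosen to give rings around a millimeter, cumulative radii of
roughly 100-300 mm, and a plot > tree > core variance ordering — the
magnitudes a dendrochronologist would call plausible for slow-grown
Mediterranean pines. Tree radii are reported as the largest core's full
cumulative growth (a measured cross-section radius can never be smaller
than a core's cumulative sum); `truncate_rings` drops inner rings while
keeping the full radius, exercising the additive rescaling path. The
climate generator uses a Mediterranean cycle (temperature peaking in July,
precipitation in winter, dry summers) over 51 calendar years, i.e. 50
complete October-September seasonal years, with a default warming trend of
0.02 degrees C per year and seeded noise.

What the generator does *not* emulate: spatial correlation between plots,
missing interior rings, measurement error distinct from process noise, and
real low-frequency climate variability. Passing tests therefore demonstrate
the correctness of the algorithms under the declared model, not the
adequacy of that model for any particular forest.

## Numerical choices and limitations

* Fixed-point solves of the growth recursion stop at a relative step below
  1e-12; fits use `nlminb` with an `optim` fallback and error out (with the
  optimizer's message) rather than silently returning non-converged
  objects.
* Degenerate inputs: empty evaluation groups, reference years outside a
  core's range, non-positive bases under fractional allometric exponents,
  constant series in the Mantel standardization, and non-finite values
  after the log transforms are all hard errors with messages naming the
  offender; a zero wet area in the aridity index is the one soft case (NA
  plus warning).
* Test problem sizes are deliberately modest — recovery experiments use
  the emulated 2 x 2 x 2 x 125-year design, calibration checks use a few
  hundred seeded replicates with 999 permutations — chosen as the smallest
  sizes at which the properties under test are statistically meaningful.
* With only two plots, plot-level variance components are estimated with
  roughly one degree of freedom. Wald-type two-standard-error intervals
  for fixed effects then undercover noticeably — a well-known small-sample
  property of the design being emulated, shared by any REML fitter, and
  visible in the parameter-recovery experiments. Inference on plot-level
  quantities from two plots should be treated with corresponding caution.
* Interior missing years inside a core break the row-order spacing that the
  ARMA correlation structure assumes; the package follows the usual
  longitudinal-model practice of treating records as consecutive within
  cores.
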