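Package: dendroflux
Title: Multilevel Modeling and Comparison of Dendroclimatic Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes multilevel dendroclimatic data series (tree-ring widths
    and monthly climate records nested in cores, trees and plots), detrends
    them with growth-theory log-linear mixed-effects models fitted by REML
    (nested random effects, ARMA within-group correlation, constant-plus-power
    variance functions), computes annual aridity indices as dry/wet area
    ratios of Walter-Lieth diagrams, and compares the detrended fluctuations
    of two data sets with Mantel correlograms and permutation tests. Includes
    seeded generators of synthetic growth and climate fixtures emulating a
    nested sampling design, plus a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
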