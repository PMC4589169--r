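Package: wmhpath
Title: Quantitative Neuropathology Pipeline for Tau, Amyloid, Small Vessel
    Disease and White Matter Hyperintensity Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a quantitative measurement chain linking cortical
    hyperphosphorylated-tau and amyloid-beta immunoreactivity burden and
    white-matter small vessel disease to white-matter-hyperintensity
    severity: DAB percent-area quantification of immunohistochemistry
    rasters with RGB colour thresholds and a physical size filter,
    sclerotic-index vessel wall morphometry, ARWMC-style lesion rating of
    binary white-matter lesion masks, and a cohort statistics battery
    (normality-routed group comparisons, age-controlled one-tailed partial
    correlations, forward stepwise linear regression). Ships a ground-truthed
    synthetic-data generator (IHC montages, annular vessel cross-sections,
    lesion masks, Gaussian-copula cohorts) so that every stage can be
    validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    MASS,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
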