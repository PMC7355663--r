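Package: melbind
Title: Melanin Binding Analysis from Microscale Thermophoresis and
    Equilibrium Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies small-molecule binding to melanin from two
    complementary assays and extrapolates the results to pigmented tissue.
    Microscale-thermophoresis (MST) dilution series are reduced to
    dose-response points (hot/cold region selection, normalized
    fluorescence, initial-fluorescence mode detection) and fitted with a
    quadratic ligand-depletion binding model to estimate dissociation
    constants with 68% confidence intervals.  Traditional
    equilibrium-binding data (supernatant depletion) are converted to bound
    amounts and fitted with the Sips (Langmuir-Freundlich) isotherm.
    Fitted parameters are translated into unbound drug fractions at
    arbitrary melanin concentrations -- including the human RPE-choroid --
    by mass-balance root finding or dilution scaling, and compounds are
    assigned to four melanin-binding classes.  Cross-method comparison
    statistics (target-capacity ratios, Spearman correlation,
    through-origin regression) and a seeded synthetic-data generator for
    both assays are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
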