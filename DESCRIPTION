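Package: silencescreen
Title: Simulation and Analysis of a Pooled Silencing-Loss Longevity Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse a genome-scale pooled screen for
    long-lived yeast deletion mutants based on age-dependent loss of
    transcriptional silencing under 5-fluoroorotic acid (5-FOA)
    counter-selection. Provides seeded generators for barcoded deletion
    libraries with planted lifespan effects, a branching-process simulator of
    serially reseeded +/-5-FOA pooled cultures with a deterministic
    expected-count mode and a stochastic multinomial mode, a two-channel
    barcode-array layer with median-centred log2 Cy5:Cy3 ratios and the
    long-lived classification rule with a control-library false-positive
    filter, and the validation statistics used for single-strain follow-up:
    replicative-lifespan summaries with the eight-point flanking Mann-Whitney
    U procedure (exact enumeration and tie-corrected normal approximation)
    and reproductive-span curves with sterile exclusion, matricide censoring
    and the Mantel-Cox log-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
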