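Package: rhythmdiff
Title: Differential Analysis of Diurnal Rhythms in Omics Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and between-group comparison of 24-hour rhythms in
    feature-by-sample omics time courses. Provides cosinor harmonic
    regression, a JTK-style Kendall-tau template test and a Lomb-Scargle
    periodogram test with a configurable consensus rule; joint nonlinear
    differential-cosinor fits comparing mesor, amplitude and acrophase
    between two groups with gating and class assignment; circular phase
    statistics and Kuiper-test phase set enrichment with process-level
    phase summarisation; hypergeometric over-representation analysis;
    a simplified negative-binomial differential-expression test (global
    and time-adjusted); a shorthand lipid-nomenclature parser and class
    profiling; and a synthetic two-group diurnal data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
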