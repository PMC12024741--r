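Package: shaftqc
Title: Quality Evaluation of Degraded DNA from Hair Shafts and Other
    Non-Invasive Samples
Version: 0.1.0
Authors@R:
    person("shaftqc", "developers", email = "shaftqc@example.org",
           role = c("aut", "cre"))
Description: Alignment-derived quality control for highly fragmented,
    low-endogenous DNA such as that recovered from rootless hair shafts.
    Computes per-sample endogenous-content metrics (mapping rate R_m,
    multi-mapping ratio R_m0, mean read length A_L), read-length-stratified
    mapping analysis with trend regression, terminal cytosine-deamination
    damage profiles reconstructed from MD tags or a reference (with the
    damage statistics N_db, R_dm and the coefficient of variation across
    samples), and a normality-gated group-comparison procedure. Includes a
    synthetic degraded-read simulator with per-read ground truth so every
    stage is verifiable by parameter recovery, plus a study pipeline and
    command-line interface producing TSV/JSON report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
Config/testthat/edition: 3
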