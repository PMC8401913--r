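Package: pkassay
Title: Bioanalytical Method Validation and Noncompartmental
    Pharmacokinetics for LC-MS/MS Plasma Assays
Version: 0.1.0
Authors@R:
    person("Assay", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Internal-standard calibration, back-calculation and
    quantification for MRM (multiple-reaction-monitoring) LC-MS/MS plasma
    assays; the full bioanalytical validation battery (accuracy,
    within/between-run precision, matrix factor, carryover, stability,
    dilution integrity) with configurable acceptance thresholds;
    chromatographic peak integration and signal-to-noise based LLOQ
    determination; and noncompartmental pharmacokinetic analysis (terminal
    slope, half-life, trapezoidal AUC/AUMC, MRT, Vd, Cl, absolute
    bioavailability). Ships a synthetic-data generator (one-compartment IV
    bolus and Bateman oral models, Gaussian MRM peaks) so the whole
    pipeline is testable end to end without instrument data, plus a small
    command-line front end for reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
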