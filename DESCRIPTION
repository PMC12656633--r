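Package: purslaneNIR
Title: NIR Chemometrics for Oxalate and Organic Acids in Purslane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Near-infrared (900-1700 nm) chemometrics pipeline for
    non-destructive assessment of total oxalate, ascorbic acid and organic
    acids in purslane (Portulaca oleracea L.). Provides spectral
    preprocessing (Savitzky-Golay second derivative, multiplicative scatter
    correction), from-scratch PLS1 (NIPALS) calibration with leave-one-out
    cross-validation and SEC/SECV/r/RPD reporting, aquaphotomics aquagrams
    at water-matrix coordinates, summary-level treatment statistics
    (percent oxalate reduction, one-way ANOVA eta-squared), and a seeded
    synthetic spectra generator emulating the study design for fully
    reproducible testing.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
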