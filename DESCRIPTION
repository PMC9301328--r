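Package: trfnet
Title: Source-Space Temporal Response Function Brain Networks from
    Multi-Subject EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the brain tracks continuous speech with
    electroencephalography (EEG): cross-subject functional hyperalignment by
    multi-set canonical correlation analysis (MCCA) with additive averaging,
    standardized minimum-norm (sLORETA) source reconstruction with
    region-of-interest aggregation, temporal response function (TRF)
    encoder/decoder estimation with leave-one-out stimulus reconstruction,
    TRF-correlation brain networks with signed-modularity community
    detection, and variation-of-information multi-scale selection.  Includes
    a seeded forward simulator of multi-subject, multi-trial EEG with
    planted community structure so the whole pipeline is testable end to
    end without any recorded data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
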