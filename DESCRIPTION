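Package: grscreen
Title: Growth-Rate Inhibition Metrics for High-Throughput Drug-Response Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for normalized growth rate inhibition (GR)
    analysis of endpoint viability screens: background correction and robust
    averaging of raw plate luminescence readouts, per-condition GR values,
    constrained sigmoidal dose-response fits with a flat-fit F-test fallback,
    the six GR metrics (GR50, GRmax, GRAOC, GRinf, hGR, GEC50) with their
    edge-case censoring rules, division-rate quality-control filters,
    replicate averaging with SEM statistics, and per-drug / per-drug-class
    aggregate summaries. Includes a synthetic plate simulator with known
    ground truth so the full pipeline and parameter recovery are testable
    without external data, and a traditional IC50/Emax contrast that
    demonstrates the division-rate confounding GR metrics remove.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
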