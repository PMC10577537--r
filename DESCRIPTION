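Package: icclock
Title: Intersection Clocks for Epigenetic Age Prediction from Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts epigenetic age from CpG-level bisulfite-sequencing
    methylation calls using per-sample "intersection clocks": for every test
    sample the CpG sites shared between a training cohort and that sample are
    determined, an ensemble of elastic-net clocks is retrained on exactly
    those sites by fivefold cross-validation, and the ensemble mean is the
    predicted age.  This guarantees no missing clock sites at prediction time,
    which matters for RRBS/WGBS data where site coverage varies strongly
    between studies.  Includes readers for Bismark-style CpG reports and
    processed methylation tables (with strand collapsing and coverage
    filtering), a pluggable coordinate-mapping layer, group-comparison
    statistics for detecting rejuvenation events, and a synthetic-data
    generator for testing the full workflow without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
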