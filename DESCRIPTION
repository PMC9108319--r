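Package: recipro
Title: Reciprocal-Transplant Analysis of Local Adaptation in Maize Landraces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for elevational reciprocal-transplant common-garden
    experiments with maize landraces. Provides a synthetic-data generator that
    emulates a four-population (continent by elevation) design with latitude-paired
    accessions, derived fitness metrics (FITplant, FITplantveg, barrenness,
    anthesis-silking interval, delta 13C), per-SNP Hudson F_ST and genotype PCA,
    REML variance partitioning and Q_ST versus F_ST divergence scans with the
    mean + 2 SD rule, genotype-by-environment reaction-norm contrasts with
    Satterthwaite t-ratios, quadratic environmental-distance fitness-decay tests,
    and garden-specific trait correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
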