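Package: biphasr
Title: Biphasic Dose-Response Analysis for Multi-Driver Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits the three-parameter Hill equation and a two-site biphasic
    inhibition model to cancer-cell viability dose-response data, decomposing
    drug action into a high-affinity target-specific phase (F1, Kd1) and a
    low-affinity off-target phase (F2, Kd2).  Joint Hill/biphasic fits are
    used to classify cell lines as mono-driver or multi-driver, and 1:1 drug
    combinations are quantified and ranked with empirical ICx estimates,
    Chou-Talalay dose-reduction indices, combination indices, and
    isobolograms.  Includes plate-level viability normalization for MTT-style
    assays and GDSC-style screening tables, and a seeded synthetic plate-data
    generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
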