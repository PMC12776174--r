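Package: placomp
Title: Compositional Deviation and Spatial Analysis of Single-Cell Placental Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream quantitative analysis of per-nucleus prediction tables
    from single-cell-resolution placental histology: nucleus deduplication and
    syncytial-knot post-processing, tissue-area estimation, cell-type and
    tissue-structure densities and compositions, slide-level deviation from a
    bootstrap-calibrated healthy reference measured by the Aitchison distance
    on centred log-ratio transformed compositions, local spatial
    autocorrelation maps of target classes, and the group-level statistical
    comparisons (Kolmogorov-Smirnov, Mann-Whitney, rank correlations with
    Bonferroni correction). Includes a seeded synthetic slide generator that
    emulates the statistical structure of such prediction tables so the whole
    pipeline is testable without clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
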