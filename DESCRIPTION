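Package: costimr
Title: Single-Cell Dissection of Macrophage Responses to Opposing
    Polarization Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-cell studies of macrophages
    co-stimulated with opposing polarization cues (an inflammatory M1-type
    stimulus and a resolving M2-type stimulus). Derives stimulus-specific
    core gene programs and unique core genes (UCGs) from UMI count
    matrices via Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction; classifies cross-regulation of UCGs
    under co-stimulation; quantifies expression noise with Fano factors
    and co-expression structure with significance-masked Spearman
    networks; detects mutually exclusive ("orthogonal") expression via
    binarization and significance-masked pairwise log2 odds ratios with
    Fisher's exact test; assigns dominance states to co-stimulated cells
    with a one-vs-rest multilayer-perceptron classifier; and processes
    microwell single-cell secretion chips (local zero-cell background
    normalization, 99th-percentile thresholding, arcsinh transform,
    co-secretion quantification, consensus ensemble clustering).
    Includes negative-binomial count and secretion-chip simulators that
    plant known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
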