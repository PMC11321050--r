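Package: aneukit
Title: Karyotype Inference and Aneuploidy Statistics for Single Cells,
    Metaphase Spreads, and Centromere-Foci Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying whole-chromosome aneuploidy in
    non-transformed epithelial organoid models. Infers per-cell chromosome
    gains and losses from single-cell RNA-seq count matrices using
    chromosome-level expression scores, median-deviation ratios and a
    permutation null over gene-chromosome assignments; computes karyotype
    complexity and heterogeneity statistics from metaphase-spread
    chromosome counts; tests per-chromosome missegregation frequencies
    against an exact binomial model; scores gene-expression programs (such
    as the p53 pathway) per cell with expression-matched control genes;
    and counts chromosomes per nucleus in centromere-marker fluorescence
    images by Otsu segmentation and intensity-ratio cluster counting.
    Ships synthetic-data generators with ground truth for every stage so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
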