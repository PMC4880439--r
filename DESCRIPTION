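Package: snvconsensus
Title: Calibrated Consensus Prediction of Deleterious Single-Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for building calibrated ensemble classifiers of
    single-nucleotide variant (SNV) deleteriousness from the raw scores of
    external prediction tools. Variants are assigned to five genomic
    categories (regulatory, splicing, missense, synonymous, nonsense) from
    gene models and reference sequence; per-tool, per-category decision
    thresholds are learned by maximizing normalized (balanced) accuracy;
    raw scores are transformed to uniform 0-99 confidence values via a
    binned, smoothed observed-accuracy calibration; and tools are combined
    by a confidence-weighted majority vote with per-category tool-subset
    selection and consensus re-calibration. Includes builders for balanced,
    leakage-controlled train/test datasets (distance-matched neutral
    controls, date-based splits, identity-clustered exonic splits),
    evaluation metrics, and synthetic-data generators for scores and a
    miniature annotated genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
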