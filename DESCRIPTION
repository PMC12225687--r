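Package: phagetcr
Title: Phage Display TCR Screening: Motif Deconvolution, Specificity
    Prediction, and Repertoire Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for phage-display screens of T cell receptors
    (TCRs) with randomized CDR3beta loops panned against a peptide-MHC
    target. Simulates input libraries and panning outputs with planted
    binding motifs, applies clonotype-level quality filters to screen
    sequencing output, deconvolves position weight matrix (PWM) binding
    motifs from background contamination with a mixture-model EM fitted
    against a fixed flat background, trains a transformer-encoder sequence
    classifier on screen-derived binders versus input-library non-binders,
    mines TCR repertoires for epitope-specific candidates, benchmarks the
    classifier against exact-match and BLOSUM62 similarity/distance
    baselines by ROC AUC, and scans a proteome for self-peptides with high
    similarity to a query epitope as cross-reactivity candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
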