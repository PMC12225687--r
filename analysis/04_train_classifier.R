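#!/usr/bin/env Rscript
# Train the transformer-encoder classifier on deconvolved binders
# (positives) versus input-library clonotypes never observed in the
# panned output (negatives), then run a stratified fivefold
# cross-validation — the quality-control step of the screen analysis.
#
# Writes results/classifier.rds (R object, regenerable from this
# script), results/cv_auc.tsv and results/cv_roc.tsv.

library(phagetcr)

seed <- 42L
positives <- readr::read_tsv("results/deconvolved_binders.tsv",
                             show_col_types = FALSE)$cdr3_aa
input <- read_clonotype_table("results/input_library.tsv", "mixcr")
output <- read_clonotype_table("results/panned_output.tsv", "mixcr")
negatives <- setdiff(input$cdr3_aa, output$cdr3_aa)

config <- classifier_config(embedding_dim = 32L, n_layers = 1L,
                            ff_dim = 64L, max_epochs = 30L,
                            patience = 6L, seed = seed + 20L)
fit <- train_classifier(positives, negatives, config)
print(fit)
saveRDS(fit, "results/classifier.rds")

cv <- crossvalidate(positives, negatives, n_folds = 5L, config = config)
print(cv)
readr::write_tsv(tibble::tibble(fold = seq_along(cv$fold_auc),
                                auc = cv$fold_auc),
                 "results/cv_auc.tsv")
roc <- dplyr::bind_rows(lapply(seq_along(cv$roc), function(k) {
  tibble::tibble(fold = k, cv$roc[[k]])
}))
readr::write_tsv(roc, "results/cv_roc.tsv")
cat(sprintf("Fivefold CV mean AUC: %.3f\n", cv$mean_auc))
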