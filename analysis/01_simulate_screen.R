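#!/usr/bin/env Rscript
# Simulate the phage-display screen: a randomized CASS|core|GELFF input
# library (core lengths 5/7/9), one round of panning against a planted
# multi-length binding motif (hydrophobic position 2, Gly position 3),
# and a TRBV6-5/TRBJ2-2 repertoire for later mining.
#
# Outputs under results/: input_library.tsv, panned_output.tsv (MiXCR-style),
# panned_truth.tsv (ground-truth labels), repertoire.tsv (AIRR).

library(phagetcr)

seed <- 42L
dir.create("results", showWarnings = FALSE)

design <- library_design()
cfg <- screen_sim_config(seed = seed)   # 10k input, 5k output, phi = 0.5
motif <- planted_motif()                # shared motif at lengths 5/7/9

input <- sample_input_library(design, cfg)
screen <- simulate_panning(input, motif, cfg, design)

write_clonotype_table(input, "results/input_library.tsv", "mixcr")
write_clonotype_table(screen$output_table, "results/panned_output.tsv",
                      "mixcr")
write_truth_sidecar(screen, "results/panned_truth.tsv")

rep_cfg <- repertoire_sim_config(n_records = 30000L, seed = seed)
repertoire <- generate_repertoire(rep_cfg, design)
readr::write_tsv(repertoire[, c("junction_aa", "v_call", "j_call",
                                "duplicate_count")],
                 "results/repertoire.tsv")

cat("Input library :", nrow(input), "unique clonotypes\n")
cat("Panned output :", nrow(screen$output_table), "clonotypes (",
    sum(screen$truth$label == "binder"), "true binders )\n")
cat("Repertoire    :", nrow(repertoire), "records\n")
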