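#!/usr/bin/env Rscript
# Scan a proteome for self-peptides resembling the NY-ESO-1 epitope
# SLLMWITQC: enumerate all 9-mers, filter by predicted HLA-A*02:01
# binding (heuristic anchor stand-in here; plug in an external %rank
# TSV for real predictions), require the TCR-critical residues W5/Q8,
# and rank by BLOSUM62 similarity.
#
# Uses a synthetic proteome with the three peptides the screen's TCRs
# were tested against planted in it; swap in a real proteome FASTA to
# scan for actual cross-reactivity candidates.
#
# Writes results/xreact_candidates.tsv.

library(phagetcr)

seed <- 42L
proteome <- synthetic_proteome(
  n_proteins = 60L, length_range = c(120L, 600L),
  plant = c("FLTLWLTQV", "GLRMWIKQV", "TQIQWATQV"),
  seed = seed + 50L)

cfg <- scan_config(rank_source = list(mode = "heuristic"))
cand <- enumerate_peptides(proteome)
cat("Enumerated", nrow(cand), "9-mer windows from",
    length(proteome), "proteins\n")
kept <- filter_binders(cand, cfg)
cat(nrow(kept), "windows pass the binding filter\n")
report <- rank_candidates(kept, top_n = 25L, cfg = cfg)
readr::write_tsv(report, "results/xreact_candidates.tsv")

cat("\nTop cross-reactivity candidates (W5/Q8 enforced):\n")
print(utils::head(report, 10L), n = 10)
cat(sprintf("\nEpitope self-similarity: %d\n",
            as.integer(similarity_to_epitope(cfg$epitope, cfg))))
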