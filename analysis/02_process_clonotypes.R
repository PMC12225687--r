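#!/usr/bin/env Rscript
# Quality-filter the screen output (alphabet, singleton, template,
# dedup) and extract per-length randomized cores for input and output.
# Writes results/output_cores.tsv, results/input_cores.tsv and a
# per-filter audit results/filter_audit.json.

library(phagetcr)

design <- library_design()
input <- read_clonotype_table("results/input_library.tsv", "mixcr")
output <- read_clonotype_table("results/panned_output.tsv", "mixcr")

input_filt <- filter_clonotypes(input, "YVGNT", design)
output_filt <- filter_clonotypes(output, "YVGNT", design)

input_cores <- extract_cores(input_filt, design)
output_cores <- extract_cores(output_filt, design)

readr::write_tsv(core_set_table(input_cores), "results/input_cores.tsv")
readr::write_tsv(core_set_table(output_cores), "results/output_cores.tsv")
jsonlite::write_json(
  list(input = as.list(attr(input_filt, "audit")),
       output = as.list(attr(output_filt, "audit"))),
  "results/filter_audit.json", auto_unbox = TRUE, pretty = TRUE)

cat("Output filter audit:\n")
print(attr(output_filt, "audit"))
print(output_cores)
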