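# data-raw

Not distributed: this directory is the drop-in location for the study's
supplementary sequencing exports, which must be downloaded from the
journal and are not redistributable with the package.

Expected layout for `reproduce_screen_counts()` and the real-data
acceptance check:

    data-raw/screen_exports/1g4_input.tsv
    data-raw/screen_exports/1g4_output.tsv
    data-raw/screen_exports/1g4-c50_input.tsv
    data-raw/screen_exports/1g4-c50_output.tsv
    data-raw/screen_exports/1g4-c53c50_input.tsv
    data-raw/screen_exports/1g4-c53c50_output.tsv

Each file is a MiXCR-style clonotype TSV (columns `cloneCount`,
`aaSeqCDR3`, `allVHitsWithScore`, `allJHitsWithScore`) for the unselected
input library and the pooled panned output of one template.
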