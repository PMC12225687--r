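#' Recompute per-template binder counts from real screen exports
#'
#' Reproduces the screen's headline sequence counts from the published
#' supplementary sequencing data, which must be downloaded separately
#' and is not redistributed with the package. Expected layout under
#' `data_dir`: for each template name (default the three screen
#' templates), a MiXCR-style clonotype TSV `<template>_input.tsv` for
#' the unselected library and `<template>_output.tsv` for the pooled
#' panned output. Each template's output is quality-filtered
#' ([filter_clonotypes()]), split into per-length cores, and
#' deconvolved against its input background ([deconvolve_cores()]);
#' the unique deconvolved binder CDR3beta sequences are counted per
#' template and after pooling all templates (duplicates removed).
#'
#' @param data_dir directory containing the per-template TSV files.
#' @param templates template names to process.
#' @param template_core core of the un-randomized template sequence.
#' @param design a [library_design()].
#' @param seed seed for the deconvolution restarts.
#' @return List with `per_template` (named unique-binder counts),
#'   `combined` (pooled dedup count) and `binders` (per-template
#'   sequence vectors).
#' @export
reproduce_screen_counts <- function(data_dir,
                                    templates = c("1g4", "1g4-c50",
                                                  "1g4-c53c50"),
                                    template_core = "YVGNT",
                                    design = library_design(),
                                    seed = 1L) {
  paths <- lapply(templates, function(tm) {
    list(input = file.path(data_dir, paste0(tm, "_input.tsv")),
         output = file.path(data_dir, paste0(tm, "_output.tsv")))
  })
  names(paths) <- templates
  missing <- unlist(lapply(paths, function(p) {
    unlist(p)[!file.exists(unlist(p))]
  }), use.names = FALSE)
  if (length(missing) > 0L) {
    stop("screen sequencing export(s) not found (download the study's ",
         "supplementary data and place the per-template clonotype ",
         "tables in ", data_dir, "); missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  binders <- lapply(templates, function(tm) {
    inp <- read_clonotype_table(paths[[tm]]$input, "mixcr")
    out <- read_clonotype_table(paths[[tm]]$output, "mixcr")
    input_cores <- extract_cores(
      filter_clonotypes(inp, template_core, design), design)
    output_cores <- extract_cores(
      filter_clonotypes(out, template_core, design), design)
    res <- deconvolve_cores(output_cores, input_cores, seed = seed)
    paste0(design$flank_n,
           unlist(lapply(res, `[[`, "binders"), use.names = FALSE),
           design$flank_c)
  })
  names(binders) <- templates
  list(
    per_template = vapply(binders, function(b) length(unique(b)), 0L),
    combined = length(unique(unlist(binders, use.names = FALSE))),
    binders = binders
  )
}
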