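#' Quality-filter phage-screen clonotypes
#'
#' Applies the screen's clonotype-level quality filters, in a fixed order:
#'
#' 1. **alphabet** — drop sequences containing non-standard amino acids;
#' 2. **singleton** — drop clonotypes with read count 1, which are likely
#'    sequencing errors;
#' 3. **template** — drop sequences whose randomized core equals the
#'    template core (i.e. the full CDR3beta `flank_n + template_core +
#'    flank_c`), which reflect template molecules that escaped
#'    randomization;
#' 4. **dedup** — collapse identical amino-acid sequences to unique
#'    clonotypes with summed read counts.
#'
#' Deduplication runs last so that summing counts cannot ambiguously
#' resurrect removed singletons. Per-filter removal tallies are attached as
#' attribute `audit` (a named integer vector with `input`, one entry per
#' filter, and `kept`).
#'
#' @param table clonotype tibble (columns `cdr3_aa`, `count`, ...).
#' @param template_core core sequence of the (un-randomized) template, e.g.
#'   `"YVGNT"`; set `NULL` to disable the template filter.
#' @param design [library_design()] supplying the flanks that embed the
#'   template core.
#' @return Filtered clonotype tibble with an `audit` attribute.
#' @export
filter_clonotypes <- function(table, template_core = "YVGNT",
                              design = library_design()) {
  n_input <- nrow(table)

  ok_alpha <- is_standard_aa(table$cdr3_aa)
  n_alpha <- sum(!ok_alpha)
  table <- table[ok_alpha, , drop = FALSE]

  ok_count <- table$count >= 2L
  n_single <- sum(!ok_count)
  table <- table[ok_count, , drop = FALSE]

  n_template <- 0L
  if (!is.null(template_core) && nzchar(template_core)) {
    template_cdr3 <- paste0(design$flank_n, template_core, design$flank_c)
    ok_template <- table$cdr3_aa != template_cdr3
    n_template <- sum(!ok_template)
    table <- table[ok_template, , drop = FALSE]
  }

  n_before_dedup <- nrow(table)
  if (nrow(table) > 0L) {
    counts <- rowsum(table$count, group = table$cdr3_aa, reorder = FALSE)
    first <- !duplicated(table$cdr3_aa)
    dedup <- table[first, , drop = FALSE]
    dedup$count <- as.integer(counts[match(dedup$cdr3_aa, rownames(counts)),
                                     1])
    table <- dedup
  }
  n_dedup <- n_before_dedup - nrow(table)

  attr(table, "audit") <- c(
    input = n_input, alphabet = n_alpha, singleton = n_single,
    template = n_template, dedup = n_dedup, kept = nrow(table)
  )
  table
}

#' Extract randomized cores from filtered clonotypes
#'
#' Every CDR3beta that begins with the design's N-flank and ends with its
#' C-flank yields the middle substring as its randomized core; all other
#' sequences (flank mismatches, or sequences too short to contain a
#' non-empty core) are excluded and tallied. Cores are partitioned by
#' length with provenance back to the source CDR3beta.
#'
#' @param table clonotype tibble (ideally from [filter_clonotypes()]).
#' @param design a [library_design()].
#' @return A `core_set`: named list of tibbles (`core`, `source_cdr3`,
#'   `count`), keyed by core length, with attributes `n_excluded` and
#'   `audit`.
#' @export
extract_cores <- function(table, design = library_design()) {
  fn <- design$flank_n
  fc <- design$flank_c
  min_len <- nchar(fn) + nchar(fc) + 1L
  ok <- startsWith(table$cdr3_aa, fn) & endsWith(table$cdr3_aa, fc) &
    nchar(table$cdr3_aa) >= min_len
  kept <- table[ok, , drop = FALSE]
  core <- substr(kept$cdr3_aa, nchar(fn) + 1L,
                 nchar(kept$cdr3_aa) - nchar(fc))
  by_len <- split(
    tibble::tibble(core = core, source_cdr3 = kept$cdr3_aa,
                   count = kept$count),
    nchar(core)
  )
  # unique cores within each length (counts summed over sources)
  by_len <- lapply(by_len, function(df) {
    counts <- rowsum(df$count, group = df$core, reorder = FALSE)
    first <- df[!duplicated(df$core), , drop = FALSE]
    first$count <- as.integer(counts[match(first$core, rownames(counts)), 1])
    first
  })
  structure(by_len,
            class = "core_set",
            n_excluded = sum(!ok),
            audit = c(input = nrow(table), flank_mismatch = sum(!ok),
                      kept = nrow(kept)))
}

#' @export
print.core_set <- function(x, ...) {
  cat("CDR3beta core set (", attr(x, "n_excluded"),
      " flank-mismatched sequence(s) excluded)\n", sep = "")
  for (len in names(x)) {
    cat("  length ", len, ": ", nrow(x[[len]]), " unique core(s)\n",
        sep = "")
  }
  invisible(x)
}

#' Flatten a core set to a tibble
#'
#' @param core_set a `core_set` from [extract_cores()].
#' @return Tibble with columns `length`, `core`, `source_cdr3`, `count`.
#' @export
core_set_table <- function(core_set) {
  dplyr::bind_rows(lapply(names(core_set), function(len) {
    tibble::tibble(length = as.integer(len), core_set[[len]])
  }))
}
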