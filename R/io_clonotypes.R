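#' Normalize a V/J gene call for matching
#'
#' Strips MiXCR-style alignment scores (`"TRBV6-5*01(1200)"`), allele
#' suffixes (`*01`), surrounding whitespace, and secondary hits after a
#' comma, and upper-cases the result, so that gene names can be compared
#' allele-insensitively. The original string should be preserved by
#' callers; this is a matching key, not a replacement.
#'
#' @param x character vector of gene call strings.
#' @return Character vector of normalized gene names (`NA` stays `NA`).
#' @export
normalize_gene_call <- function(x) {
  out <- toupper(trimws(as.character(x)))
  out <- sub(",.*$", "", out)      # keep the primary hit only
  out <- sub("\\(.*\\)", "", out)  # drop alignment score
  out <- sub("\\*.*$", "", out)    # drop allele suffix
  trimws(out)
}

# allele-insensitive gene equality
gene_matches <- function(call, gene) {
  normalize_gene_call(call) == normalize_gene_call(gene)
}

#' Read a clonotype table
#'
#' Reads either a MiXCR-style export (columns `cloneCount`, `aaSeqCDR3`,
#' `allVHitsWithScore`, `allJHitsWithScore`) or an AIRR rearrangement TSV
#' (columns `junction_aa`, `v_call`, `j_call`, `duplicate_count`) into the
#' unified clonotype tibble used throughout the package: `cdr3_aa`,
#' `count`, `v_call`, `j_call` (original strings) plus `v_gene`, `j_gene`
#' (normalized matching keys). Rows with a missing/empty sequence or an
#' unparseable count are skipped; the number skipped is attached as
#' attribute `n_skipped` and reported via a message.
#'
#' @param path file path of a tab-separated table.
#' @param dialect `"mixcr"` or `"airr"`.
#' @return Clonotype tibble.
#' @export
read_clonotype_table <- function(path, dialect = c("mixcr", "airr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cols <- switch(dialect,
    mixcr = c(seq = "aaSeqCDR3", count = "cloneCount",
              v = "allVHitsWithScore", j = "allJHitsWithScore"),
    airr = c(seq = "junction_aa", count = "duplicate_count",
             v = "v_call", j = "j_call")
  )
  missing_cols <- setdiff(unname(cols[c("seq", "count")]), names(raw))
  if (length(missing_cols) > 0L) {
    stop(dialect, " table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seq <- raw[[cols["seq"]]]
  count <- suppressWarnings(as.integer(as.numeric(raw[[cols["count"]]])))
  v <- if (cols["v"] %in% names(raw)) raw[[cols["v"]]] else NA_character_
  j <- if (cols["j"] %in% names(raw)) raw[[cols["j"]]] else NA_character_

  bad <- is.na(seq) | !nzchar(seq) | is.na(count) | count < 1L
  if (any(bad)) {
    message("read_clonotype_table: skipped ", sum(bad),
            " unparseable row(s)")
  }
  out <- tibble::tibble(
    cdr3_aa = seq[!bad],
    count = count[!bad],
    v_call = if (length(v) == 1L) rep(v, sum(!bad)) else v[!bad],
    j_call = if (length(j) == 1L) rep(j, sum(!bad)) else j[!bad]
  )
  out$v_gene <- normalize_gene_call(out$v_call)
  out$j_gene <- normalize_gene_call(out$j_call)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a clonotype table
#'
#' Writes the unified clonotype tibble as a MiXCR-style TSV (`cloneCount`,
#' `aaSeqCDR3`, `allVHitsWithScore`, `allJHitsWithScore`) or an AIRR
#' rearrangement TSV (`junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`).
#'
#' @param table clonotype tibble (or AIRR-style tibble with `junction_aa`
#'   and `duplicate_count` columns).
#' @param path output path.
#' @param dialect `"mixcr"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(table, path,
                                  dialect = c("mixcr", "airr")) {
  dialect <- match.arg(dialect)
  seq <- table[["cdr3_aa"]] %||% table[["junction_aa"]]
  count <- table[["count"]] %||% table[["duplicate_count"]]
  out <- switch(dialect,
    mixcr = tibble::tibble(
      cloneCount = count,
      aaSeqCDR3 = seq,
      allVHitsWithScore = table[["v_call"]],
      allJHitsWithScore = table[["j_call"]]
    ),
    airr = tibble::tibble(
      junction_aa = seq,
      v_call = table[["v_call"]],
      j_call = table[["j_call"]],
      duplicate_count = count
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write ground-truth labels of a simulated screen
#'
#' Sidecar TSV keyed by sequence (`cdr3_aa`, `label`) recording which
#' output clonotypes are planted binders versus contaminants.
#'
#' @param screen a `simulated_screen`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(screen, path) {
  stopifnot(inherits(screen, "simulated_screen"))
  readr::write_tsv(screen$truth, path, progress = FALSE)
  invisible(path)
}
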