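#' Experimentally tested TCR candidates for the NY-ESO-1 screen
#'
#' The published validation set of the NY-ESO-1 phage-display study: 30
#' CDR3beta sequences selected from repertoire mining to span a broad
#' range of classifier scores, plus the reference (positive-control)
#' CDR3beta `CASSYVGNTGELFF` and a randomly selected negative control,
#' each with the published model score and the percentage of
#' multimer-positive CD8+ Jurkat cells measured with the three TCR
#' templates (1G4 and the affinity-enhanced 1G4-c50 and 1G4-c53c50).
#'
#' @param include_controls keep the positive/negative control rows
#'   (default `FALSE`: the 30 mined candidates only, the set used for
#'   benchmarking).
#' @return Tibble with columns `tcr_id`, `cdr3_aa`, `model_score`,
#'   `multimer_pct_1g4`, `multimer_pct_1g4_c50`,
#'   `multimer_pct_1g4_c53c50`, `role`.
#' @export
tested_tcrs <- function(include_controls = FALSE) {
  path <- system.file("extdata", "tested_tcrs.tsv", package = "phagetcr",
                      mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = readr::cols(
    tcr_id = "c", cdr3_aa = "c", model_score = "d",
    multimer_pct_1g4 = "d", multimer_pct_1g4_c50 = "d",
    multimer_pct_1g4_c53c50 = "d", role = "c"), progress = FALSE)
  if (!include_controls) out <- out[out$role == "candidate", , drop = FALSE]
  out
}

#' Label the tested TCRs as binders/non-binders for one template
#'
#' Binary labels for benchmarking: the `n_positives` candidates with the
#' highest multimer-positive percentage for the chosen template are
#' positives, the rest negatives. For the 1G4 template, 6 of the 30
#' candidates were validated as NY-ESO-1 binders, so the default
#' reproduces that labeling.
#'
#' @param template `"1g4"`, `"1g4_c50"` or `"1g4_c53c50"`.
#' @param n_positives number of top-multimer candidates labeled positive
#'   (default 6, the validated count for the 1G4 template).
#' @return The [tested_tcrs()] tibble with an added integer `label`
#'   column (1 = binder).
#' @export
tested_tcr_labels <- function(template = c("1g4", "1g4_c50", "1g4_c53c50"),
                              n_positives = 6L) {
  template <- match.arg(template)
  tab <- tested_tcrs()
  col <- paste0("multimer_pct_", template)
  stopifnot(n_positives >= 1L, n_positives < nrow(tab))
  thr <- sort(tab[[col]], decreasing = TRUE)[n_positives]
  tab$label <- as.integer(tab[[col]] >= thr)
  if (sum(tab$label) != n_positives) {
    stop("multimer ties prevent an unambiguous top-", n_positives,
         " labeling for template ", template, call. = FALSE)
  }
  tab
}
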