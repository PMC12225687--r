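#' Filter a repertoire to the template-compatible sequence space
#'
#' Restricts an AIRR-convention repertoire table to records the screen's
#' classifier can meaningfully score: V and J genes matching the library
#' design (allele-insensitive), junctions with the template flanks
#' (`CASS`...`GELFF` by default) and only standard amino acids, and a
#' non-empty core. Duplicate junctions are collapsed (counts summed,
#' first record's gene calls kept). Per-filter removal tallies are
#' attached as attribute `audit`; the function is idempotent.
#'
#' @param table tibble with columns `junction_aa`, `v_call`, `j_call`
#'   and optionally `duplicate_count` (assumed 1 when absent).
#' @param design a [library_design()].
#' @return Filtered tibble with an added `core` column.
#' @export
filter_repertoire <- function(table, design = library_design()) {
  n_input <- nrow(table)
  dc <- table[["duplicate_count"]] %||% rep(1L, n_input)
  table$duplicate_count <- dc

  ok_v <- gene_matches(table$v_call, design$v_gene)
  ok_j <- gene_matches(table$j_call, design$j_gene)
  n_gene <- sum(!(ok_v & ok_j))
  table <- table[ok_v & ok_j, , drop = FALSE]

  ok_alpha <- is_standard_aa(table$junction_aa)
  n_alpha <- sum(!ok_alpha)
  table <- table[ok_alpha, , drop = FALSE]

  min_len <- nchar(design$flank_n) + nchar(design$flank_c) + 1L
  ok_flank <- startsWith(table$junction_aa, design$flank_n) &
    endsWith(table$junction_aa, design$flank_c) &
    nchar(table$junction_aa) >= min_len
  n_flank <- sum(!ok_flank)
  table <- table[ok_flank, , drop = FALSE]

  n_before <- nrow(table)
  if (n_before > 0L) {
    counts <- rowsum(as.integer(table$duplicate_count),
                     group = table$junction_aa, reorder = FALSE)
    dedup <- table[!duplicated(table$junction_aa), , drop = FALSE]
    dedup$duplicate_count <-
      as.integer(counts[match(dedup$junction_aa, rownames(counts)), 1])
    table <- dedup
  }
  n_dedup <- n_before - nrow(table)

  table$core <- substr(table$junction_aa, nchar(design$flank_n) + 1L,
                       nchar(table$junction_aa) - nchar(design$flank_c))
  attr(table, "audit") <- c(input = n_input, gene = n_gene,
                            alphabet = n_alpha, flank = n_flank,
                            dedup = n_dedup, kept = nrow(table))
  table
}

#' Score and rank a filtered repertoire
#'
#' Scores every record with the trained classifier and ranks descending
#' (rank 1 = highest score). Score ties are broken lexicographically by
#' junction sequence so that rankings are deterministic and stable under
#' record shuffling.
#'
#' @param model a [train_classifier()] model.
#' @param table filtered repertoire from [filter_repertoire()].
#' @return A `scored_repertoire` tibble: the input plus `score`, `rank`
#'   and `core_length`, ordered by rank.
#' @export
rank_repertoire <- function(model, table) {
  stopifnot(nrow(table) > 0L)
  score <- score_sequences(model, table$junction_aa)
  ord <- order(-score, table$junction_aa)
  out <- table[ord, , drop = FALSE]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  out$core_length <- nchar(out$core)
  class(out) <- c("scored_repertoire", class(out))
  out
}

#' Select candidate TCRs from a ranked repertoire
#'
#' Two strategies mirror how screen candidates are taken to validation:
#' `"top"` picks the `n` best-ranked records; `"broad_range"` stratifies
#' the score range into `n_strata` quantile bands, draws evenly across
#' them so that candidates span high to low scores, and then enforces
#' core-length diversity by swapping in the best-ranked record of an
#' unrepresented length when all picks share one length. Selection is
#' reproducible given `seed`.
#'
#' @param scored a [rank_repertoire()] result.
#' @param n number of candidates.
#' @param strategy `"broad_range"` or `"top"`.
#' @param n_strata quantile bands for `"broad_range"` (default 6).
#' @param seed integer seed for within-stratum draws.
#' @return Tibble of `n` selected rows (a subset of `scored`), ordered
#'   by rank.
#' @export
select_candidates <- function(scored, n, strategy = c("broad_range", "top"),
                              n_strata = 6L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (n > nrow(scored)) {
    stop("requested ", n, " candidates from ", nrow(scored), " records",
         call. = FALSE)
  }
  if (strategy == "top") {
    return(scored[seq_len(n), , drop = FALSE])
  }
  set.seed(seed)
  qs <- stats::quantile(scored$score,
                        probs = seq(0, 1, length.out = n_strata + 1L))
  stratum <- cut(scored$score, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
  per <- rep(n %/% length(unique(stratum)), length(unique(stratum)))
  extra <- n - sum(per)
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  picks <- integer()
  strata_desc <- sort(unique(stratum), decreasing = TRUE)
  for (si in seq_along(strata_desc)) {
    pool <- which(stratum == strata_desc[si])
    take <- min(per[si], length(pool))
    picks <- c(picks, sort(sample(pool))[seq_len(take)])
  }
  # top up from best remaining ranks if strata were too small
  if (length(picks) < n) {
    rest <- setdiff(seq_len(nrow(scored)), picks)
    picks <- c(picks, rest[seq_len(n - length(picks))])
  }
  picks <- sort(picks)

  # enforce core-length diversity when available
  if (length(unique(scored$core_length[picks])) < 2L &&
      length(unique(scored$core_length)) >= 2L) {
    other <- which(scored$core_length != scored$core_length[picks[1]])
    swap_in <- other[which.min(scored$rank[other])]
    picks[length(picks)] <- swap_in
    picks <- sort(unique(picks))
  }
  scored[picks, , drop = FALSE]
}
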