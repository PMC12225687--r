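#' Configuration of a cross-reactivity proteome scan
#'
#' Parameters of the self-peptide search: the query epitope, the
#' peptide-MHC binding %rank filter, and the residues required at fixed
#' positions of a candidate. The defaults target the NY-ESO-1 157-165
#' epitope SLLMWITQC on HLA-A*02:01: candidates must have predicted
#' binding %rank below 1.5 and carry Trp at position 5 and Gln at
#' position 8, the residues critical for TCR recognition.
#'
#' @param epitope query peptide (default `"SLLMWITQC"`).
#' @param rank_threshold keep peptides with %rank strictly below this
#'   (default 1.5; lower %rank = stronger predicted binder).
#' @param required_positions named character vector mapping 1-based
#'   position to required residue (default `c("5" = "W", "8" = "Q")`).
#' @param rank_source list describing where binding %ranks come from:
#'   `list(mode = "external", path = <TSV with columns peptide, rank>)`,
#'   `list(mode = "heuristic")` for the built-in HLA-A*02:01 anchor
#'   stand-in (position 2 in L/M/I/V and the C-terminal position in
#'   V/L/I/A — a crude surrogate, not equivalent to a trained
#'   peptide-MHC predictor), or `list(mode = "none")` to pass all
#'   peptides through.
#' @param on_missing_rank `"drop"` (default) or `"error"` when external
#'   ranks lack some peptides.
#' @return A `scan_config` list.
#' @export
scan_config <- function(epitope = "SLLMWITQC",
                        rank_threshold = 1.5,
                        required_positions = c("5" = "W", "8" = "Q"),
                        rank_source = list(mode = "none"),
                        on_missing_rank = c("drop", "error")) {
  stopifnot(is_standard_aa(epitope), rank_threshold > 0)
  pos <- as.integer(names(required_positions))
  if (length(required_positions) > 0L &&
      (anyNA(pos) || any(pos < 1L | pos > nchar(epitope)))) {
    stop("required_positions must be named by 1-based positions within ",
         "the epitope", call. = FALSE)
  }
  structure(
    list(epitope = epitope,
         rank_threshold = rank_threshold,
         required_positions = required_positions,
         rank_source = rank_source,
         on_missing_rank = match.arg(on_missing_rank)),
    class = "scan_config"
  )
}

#' Enumerate peptide windows of a proteome
#'
#' All length-`k` windows of every protein in a FASTA file (or named
#' character vector), with provenance. Sequences are uppercased; windows
#' containing non-standard residues are skipped (or the whole protein,
#' per `nonstandard`). Offsets are 0-based half-open internally;
#' [rank_candidates()] reports 1-based positions.
#'
#' @param proteome path to a FASTA file, or a named character vector of
#'   protein sequences.
#' @param length window length (default 9).
#' @param nonstandard `"skip_window"` (default) or `"skip_protein"`.
#' @param dedup collapse identical peptides, concatenating provenances
#'   (default `FALSE`: one row per window).
#' @return Tibble with columns `peptide`, `protein`, `offset`.
#' @export
enumerate_peptides <- function(proteome, length = 9L,
                               nonstandard = c("skip_window",
                                               "skip_protein"),
                               dedup = FALSE) {
  nonstandard <- match.arg(nonstandard)
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) {
    aas <- Biostrings::readAAStringSet(proteome)
    seqs <- stats::setNames(as.character(aas),
                            sub("\\s.*$", "", names(aas)))
  } else {
    seqs <- proteome
  }
  if (length(seqs) == 0L) {
    stop("proteome is empty", call. = FALSE)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("proteome sequences must be named", call. = FALSE)
  }
  seqs <- toupper(seqs)
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n_win <- nchar(s) - length + 1L
    if (n_win < 1L) return(NULL)
    pep <- substring(s, seq_len(n_win), seq_len(n_win) + length - 1L)
    ok <- is_standard_aa(pep)
    if (nonstandard == "skip_protein" && !all(ok)) return(NULL)
    tibble::tibble(peptide = pep[ok], protein = id,
                   offset = (seq_len(n_win) - 1L)[ok])
  })
  out <- dplyr::bind_rows(out)
  if (dedup && nrow(out) > 0L) {
    prov <- vapply(split(out$protein, out$peptide), paste, character(1),
                   collapse = ";")
    out <- out[!duplicated(out$peptide), , drop = FALSE]
    out$protein <- unname(prov[out$peptide])
  }
  out
}

#' Filter peptide candidates by predicted MHC binding
#'
#' Applies the configured %rank source: in `"external"` mode, joins a
#' TSV of `peptide` and `rank` columns and keeps peptides with rank
#' strictly below the threshold; in `"heuristic"` mode, keeps peptides
#' matching the built-in HLA-A*02:01 anchor stand-in; in `"none"` mode,
#' passes everything through with `binding_rank = NA`.
#'
#' @param candidates tibble from [enumerate_peptides()].
#' @param cfg a [scan_config()].
#' @return The filtered candidates with an added `binding_rank` column.
#' @export
filter_binders <- function(candidates, cfg = scan_config()) {
  mode <- cfg$rank_source$mode %||% "none"
  if (mode == "none") {
    candidates$binding_rank <- NA_real_
    return(candidates)
  }
  if (mode == "heuristic") {
    p2 <- substr(candidates$peptide, 2L, 2L)
    last <- nchar(candidates$peptide)
    p9 <- substr(candidates$peptide, last, last)
    keep <- p2 %in% c("L", "M", "I", "V") & p9 %in% c("V", "L", "I", "A")
    out <- candidates[keep, , drop = FALSE]
    out$binding_rank <- NA_real_
    return(out)
  }
  if (mode == "external") {
    path <- cfg$rank_source$path
    if (is.null(path) || !file.exists(path)) {
      stop("external rank_source needs an existing path", call. = FALSE)
    }
    ranks <- readr::read_tsv(path, col_types = readr::cols(
      peptide = "c", rank = "d"), progress = FALSE)
    idx <- match(candidates$peptide, ranks$peptide)
    missing <- is.na(idx)
    if (any(missing) && cfg$on_missing_rank == "error") {
      stop(sum(missing), " candidate peptide(s) have no %rank entry",
           call. = FALSE)
    }
    if (any(missing)) {
      message("filter_binders: dropped ", sum(missing),
              " peptide(s) without a %rank entry")
    }
    candidates$binding_rank <- ranks$rank[idx]
    keep <- !missing & candidates$binding_rank < cfg$rank_threshold
    return(candidates[keep, , drop = FALSE])
  }
  stop("unknown rank_source mode: ", mode, call. = FALSE)
}

#' BLOSUM62 similarity of peptides to the query epitope
#'
#' Positionwise BLOSUM62 sum against `cfg$epitope`. All peptides must
#' have the epitope's length.
#'
#' @param peptides character vector.
#' @param cfg a [scan_config()].
#' @return Numeric similarity per peptide.
#' @export
similarity_to_epitope <- function(peptides, cfg = scan_config()) {
  bad <- nchar(peptides) != nchar(cfg$epitope)
  if (any(bad)) {
    stop("peptide length must match the epitope (",
         nchar(cfg$epitope), "): ",
         paste(utils::head(peptides[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  B <- blosum62()
  er <- split_residues(cfg$epitope)[[1]]
  vapply(peptides,
         function(p) blosum_pair_sum(split_residues(p)[[1]], er, B),
         numeric(1), USE.NAMES = FALSE)
}

#' Check the required anchored residues of candidates
#'
#' @param peptides character vector.
#' @param cfg a [scan_config()].
#' @return Logical: `TRUE` where every required position carries its
#'   required residue.
#' @export
anchors_ok <- function(peptides, cfg = scan_config()) {
  if (length(cfg$required_positions) == 0L) {
    return(rep(TRUE, length(peptides)))
  }
  ok <- rep(TRUE, length(peptides))
  for (i in seq_along(cfg$required_positions)) {
    p <- as.integer(names(cfg$required_positions)[i])
    ok <- ok & substr(peptides, p, p) == cfg$required_positions[[i]]
  }
  ok
}

#' Rank cross-reactivity candidates by epitope similarity
#'
#' Rejects peptides failing any required anchored residue, annotates the
#' survivors with BLOSUM62 similarity to the epitope, and returns the
#' top of the list ordered by descending similarity (ties broken
#' lexicographically by peptide, so the report is deterministic).
#' Offsets are reported as 1-based `position`.
#'
#' @param candidates tibble from [filter_binders()] (columns `peptide`,
#'   `protein`, `offset`, optionally `binding_rank`).
#' @param top_n rows to keep (default all).
#' @param cfg a [scan_config()].
#' @return Tibble `peptide`, `protein`, `position`, `binding_rank`,
#'   `similarity`, sorted by rank.
#' @export
rank_candidates <- function(candidates, top_n = Inf,
                            cfg = scan_config()) {
  keep <- anchors_ok(candidates$peptide, cfg)
  out <- candidates[keep, , drop = FALSE]
  out$similarity <- if (nrow(out) > 0L) {
    similarity_to_epitope(out$peptide, cfg)
  } else {
    numeric()
  }
  ord <- order(-out$similarity, out$peptide)
  out <- out[ord, , drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  tibble::tibble(
    peptide = out$peptide,
    protein = out$protein,
    position = out$offset + 1L,
    binding_rank = out[["binding_rank"]] %||% rep(NA_real_, nrow(out)),
    similarity = out$similarity
  )
}

#' Generate a synthetic proteome FASTA
#'
#' Random protein sequences (uniform over the standard alphabet) with
#' optional planted peptides overwritten at random positions — a small
#' self-contained stand-in for a real proteome download, for tests and
#' the example workflow. Clearly synthetic; no biological content.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of protein lengths.
#' @param plant character vector of peptides to embed (one per protein,
#'   cycled over the first `length(plant)` proteins).
#' @param path optional FASTA output path; when `NULL` a named character
#'   vector is returned instead.
#' @param seed integer seed.
#' @return The FASTA path (invisibly) or a named character vector.
#' @export
synthetic_proteome <- function(n_proteins = 50L,
                               length_range = c(80L, 400L),
                               plant = character(), path = NULL,
                               seed = 1L) {
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("SYNPROT%03d", seq_len(n_proteins))
  for (i in seq_along(plant)) {
    p <- plant[i]
    at <- sample(nchar(seqs[i]) - nchar(p) + 1L, 1L)
    substr(seqs[i], at, at + nchar(p) - 1L) <- p
  }
  if (is.null(path)) {
    return(seqs)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
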