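the_blosum_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Integer 20 x 20 BLOSUM62 matrix over [aa_alphabet()], read from the
#' plain-text copy bundled with the package. Symmetric, with each
#' diagonal entry at least as large as every off-diagonal entry in its
#' row (diagonal dominance), which makes self-similarity maximal among
#' equal-length peptides.
#'
#' @return Named integer matrix.
#' @export
blosum62 <- function() {
  if (is.null(the_blosum_env$B)) {
    path <- system.file("extdata", "blosum62.tsv", package = "phagetcr",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, check.names = FALSE)
    B <- as.matrix(tab[, -1])
    rownames(B) <- tab[[1]]
    storage.mode(B) <- "integer"
    stopifnot(identical(rownames(B), aa_alphabet()),
              identical(colnames(B), aa_alphabet()),
              isTRUE(all.equal(B, t(B))))
    the_blosum_env$B <- B
  }
  the_blosum_env$B
}

#' Exact-match score against a reference set
#'
#' The no-model baseline: a query scores 1 if and only if it occurs
#' verbatim in the reference set (e.g. the TCRs observed in the phage
#' display output).
#'
#' @param query character vector of sequences.
#' @param reference_set character vector.
#' @return Integer vector of 0/1.
#' @export
exact_match_score <- function(query, reference_set) {
  as.integer(query %in% reference_set)
}

# split a CDR3 into flank_n / core / flank_c under a design, or NULL
split_by_flanks <- function(seq, design) {
  min_len <- nchar(design$flank_n) + nchar(design$flank_c) + 1L
  if (!startsWith(seq, design$flank_n) || !endsWith(seq, design$flank_c) ||
      nchar(seq) < min_len) {
    return(NULL)
  }
  list(n = design$flank_n,
       core = substr(seq, nchar(design$flank_n) + 1L,
                     nchar(seq) - nchar(design$flank_c)),
       c = design$flank_c)
}

# positionwise BLOSUM sum for equal-length residue vectors
blosum_pair_sum <- function(x, y, B, w = NULL) {
  s <- B[cbind(x, y)]
  if (is.null(w)) sum(s) else sum(w * s)
}

#' BLOSUM62 similarity to a reference CDR3beta
#'
#' Positionwise BLOSUM62 similarity between a query and a reference
#' sequence. Equal-length pairs are compared position by position
#' (optionally weighted). For unequal lengths both sequences must carry
#' the design flanks: the flanks are anchored and compared directly,
#' and the shorter core is slid gaplessly within the longer, taking the
#' offset with the maximum sum; unmatched core positions of the longer
#' core contribute the matrix minimum (the strongest mismatch penalty).
#'
#' @param query character vector of sequences.
#' @param reference single reference sequence
#'   (default `"CASSYVGNTGELFF"`).
#' @param weights optional positional weights, equal-length comparisons
#'   only.
#' @param design [library_design()] supplying the anchored flanks.
#' @return Numeric similarity per query.
#' @export
blosum_similarity <- function(query, reference = "CASSYVGNTGELFF",
                              weights = NULL,
                              design = library_design()) {
  B <- blosum62()
  bmin <- min(B)
  ref_res <- split_residues(reference)[[1]]
  ref_parts <- split_by_flanks(reference, design)
  vapply(query, function(q) {
    q_res <- split_residues(q)[[1]]
    if (length(q_res) == length(ref_res)) {
      if (!is.null(weights) && length(weights) != length(ref_res)) {
        stop("weights must have one entry per position", call. = FALSE)
      }
      return(blosum_pair_sum(q_res, ref_res, B, weights))
    }
    if (!is.null(weights)) {
      stop("positional weights are defined for equal-length comparisons ",
           "only", call. = FALSE)
    }
    q_parts <- split_by_flanks(q, design)
    if (is.null(q_parts) || is.null(ref_parts)) {
      stop("unequal-length similarity needs design flanks on both ",
           "sequences: ", q, call. = FALSE)
    }
    flank_sum <-
      blosum_pair_sum(split_residues(q_parts$n)[[1]],
                      split_residues(ref_parts$n)[[1]], B) +
      blosum_pair_sum(split_residues(q_parts$c)[[1]],
                      split_residues(ref_parts$c)[[1]], B)
    a <- split_residues(q_parts$core)[[1]]
    b <- split_residues(ref_parts$core)[[1]]
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    gap <- length(b) - length(a)
    best <- max(vapply(0:gap, function(o) {
      blosum_pair_sum(a, b[(1 + o):(o + length(a))], B)
    }, numeric(1)))
    flank_sum + best + gap * bmin
  }, numeric(1), USE.NAMES = FALSE)
}

# per-position substitution cost of the tcrdist-style distance
tcrdist_cost <- function(x, y, B) {
  ifelse(x == y, 0, pmin(4, 4 - B[cbind(x, y)]))
}

#' tcrdist-style CDR3 distance
#'
#' A distance between two CDR3beta sequences in the spirit of tcrdist:
#' per aligned position, cost 0 for identity and `min(4, 4 - BLOSUM62)`
#' for a substitution; each unaligned position under the flank-anchored
#' gapless core alignment (the offset minimizing total cost) counts as a
#' gap at cost 4; the total is multiplied by the CDR3 weight 3.
#' Symmetric, zero iff the sequences are identical. A simplification of
#' tcrdist, not a bit-compatible reimplementation.
#'
#' @param a,b sequences (vectorized over `a` if `b` is scalar, and
#'   pairwise when both have the same length > 1).
#' @param design [library_design()] for the flank-anchored alignment of
#'   unequal-length pairs.
#' @param cdr3_weight multiplier applied to the summed cost (default 3).
#' @param gap_cost cost per unaligned position (default 4).
#' @return Numeric distance(s).
#' @export
cdr3_distance <- function(a, b, design = library_design(),
                          cdr3_weight = 3, gap_cost = 4) {
  B <- blosum62()
  one <- function(x, y) {
    xr <- split_residues(x)[[1]]
    yr <- split_residues(y)[[1]]
    if (length(xr) == length(yr)) {
      return(cdr3_weight * sum(tcrdist_cost(xr, yr, B)))
    }
    xp <- split_by_flanks(x, design)
    yp <- split_by_flanks(y, design)
    if (is.null(xp) || is.null(yp)) {
      # no shared flank structure: best gapless offset of the full strings
      ar <- xr; br <- yr
      if (length(ar) > length(br)) { tmp <- ar; ar <- br; br <- tmp }
      gap <- length(br) - length(ar)
      core_cost <- min(vapply(0:gap, function(o) {
        sum(tcrdist_cost(ar, br[(1 + o):(o + length(ar))], B))
      }, numeric(1)))
      return(cdr3_weight * (core_cost + gap * gap_cost))
    }
    flank_cost <-
      sum(tcrdist_cost(split_residues(xp$n)[[1]],
                       split_residues(yp$n)[[1]], B)) +
      sum(tcrdist_cost(split_residues(xp$c)[[1]],
                       split_residues(yp$c)[[1]], B))
    ar <- split_residues(xp$core)[[1]]
    br <- split_residues(yp$core)[[1]]
    if (length(ar) > length(br)) { tmp <- ar; ar <- br; br <- tmp }
    gap <- length(br) - length(ar)
    core_cost <- min(vapply(0:gap, function(o) {
      sum(tcrdist_cost(ar, br[(1 + o):(o + length(ar))], B))
    }, numeric(1)))
    cdr3_weight * (flank_cost + core_cost + gap * gap_cost)
  }
  if (length(b) == 1L) {
    vapply(a, one, numeric(1), y = b, USE.NAMES = FALSE)
  } else {
    stopifnot(length(a) == length(b))
    mapply(one, a, b, USE.NAMES = FALSE)
  }
}

#' Benchmark scoring methods on a labeled TCR set
#'
#' Evaluates each method by ROC AUC on a labeled set, the harness used
#' to compare the trained classifier with similarity baselines.
#' Distance-type methods are negated before AUC so that larger always
#' means more binder-like.
#'
#' @param labeled tibble/data.frame with columns `cdr3_aa` and `label`
#'   (1 = binder); both classes must be present.
#' @param methods named list; each element is either a function
#'   `f(seqs) -> scores` or a list `list(score = f, type = "similarity")`
#'   with `type` one of `"similarity"` (default) or `"distance"`.
#' @return Tibble with columns `method`, `auc`, `n_pos`, `n_neg`.
#' @export
benchmark_methods <- function(labeled, methods) {
  stopifnot(all(c("cdr3_aa", "label") %in% names(labeled)),
            length(methods) > 0L, !is.null(names(methods)))
  label <- as.integer(labeled$label)
  rows <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    if (is.function(m)) m <- list(score = m, type = "similarity")
    sc <- m$score(labeled$cdr3_aa)
    if (identical(m$type, "distance")) sc <- -sc
    tibble::tibble(method = nm,
                   auc = compute_auc(sc, label),
                   n_pos = sum(label == 1L),
                   n_neg = sum(label == 0L))
  })
  dplyr::bind_rows(rows)
}
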