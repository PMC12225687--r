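#' Default amino-acid composition of the randomized CDR3beta core
#'
#' Stand-in composition for the randomized core of the input phage library.
#' The true screen used a trimer-codon mixture designed to approximate the
#' residue usage of natural CDR3beta loops; those exact frequencies are not
#' redistributable, so the default here is a documented stand-in with the
#' same qualitative features: mild enrichment of Gly and Ser, no Cys (which
#' would form spurious disulfides in a displayed loop), and otherwise broad
#' coverage of the remaining residues. Fully overridable via
#' [library_design()].
#'
#' @return Named numeric vector over the 20 standard amino acids summing
#'   to 1.
#' @export
default_core_composition <- function() {
  comp <- c(
    A = 0.065, R = 0.055, N = 0.060, D = 0.055, C = 0.000,
    Q = 0.050, E = 0.055, G = 0.110, H = 0.035, I = 0.040,
    L = 0.075, K = 0.035, M = 0.020, F = 0.040, P = 0.045,
    S = 0.085, T = 0.060, W = 0.020, Y = 0.045, V = 0.050
  )
  comp[aa_alphabet()]
}

#' Design of a randomized-CDR3beta phage library
#'
#' Describes the fixed flanks, randomized core lengths, core amino-acid
#' composition, and V/J gene context of a randomized-CDR3beta library built
#' on a TCR scaffold. The defaults mirror the NY-ESO-1 screen design:
#' CDR3beta of the form `CASS` + core + `GELFF`, cores of length 5, 7 or 9,
#' on a TRBV6-5 / TRBJ2-2 chain.
#'
#' @param flank_n N-terminal fixed flank (default `"CASS"`).
#' @param flank_c C-terminal fixed flank (default `"GELFF"`).
#' @param core_lengths integer vector of randomized core lengths
#'   (default `c(5, 7, 9)`).
#' @param aa_composition named numeric vector over the 20 standard amino
#'   acids giving the per-position core composition, or a named list of such
#'   vectors keyed by core length (as character) for length-specific
#'   compositions. Default [default_core_composition()].
#' @param v_gene,j_gene V/J gene names of the scaffold chain.
#' @param allele_suffix if `TRUE`, gene names are emitted with the `*01`
#'   allele suffix by the simulators (exercises allele-insensitive matching
#'   downstream).
#'
#' @return An object of class `library_design`.
#' @export
library_design <- function(flank_n = "CASS",
                           flank_c = "GELFF",
                           core_lengths = c(5L, 7L, 9L),
                           aa_composition = default_core_composition(),
                           v_gene = "TRBV6-5",
                           j_gene = "TRBJ2-2",
                           allele_suffix = FALSE) {
  stopifnot(is.character(flank_n), length(flank_n) == 1L,
            is.character(flank_c), length(flank_c) == 1L)
  core_lengths <- sort(unique(as.integer(core_lengths)))
  if (length(core_lengths) == 0L || any(core_lengths <= 0L)) {
    stop("core_lengths must be positive integers", call. = FALSE)
  }
  if (is.list(aa_composition)) {
    comp <- lapply(aa_composition, validate_composition)
    missing_len <- setdiff(as.character(core_lengths), names(comp))
    if (length(missing_len) > 0L) {
      stop("aa_composition list lacks core length(s): ",
           paste(missing_len, collapse = ", "), call. = FALSE)
    }
  } else {
    comp <- validate_composition(aa_composition)
  }
  structure(
    list(flank_n = flank_n, flank_c = flank_c,
         core_lengths = core_lengths, aa_composition = comp,
         v_gene = v_gene, j_gene = j_gene,
         allele_suffix = isTRUE(allele_suffix)),
    class = "library_design"
  )
}

# check a composition vector: named over the 20-aa alphabet, non-negative,
# sums to 1 within 1e-9; returns it reordered to aa_alphabet()
validate_composition <- function(comp) {
  aa <- aa_alphabet()
  if (is.null(names(comp)) || !setequal(names(comp), aa)) {
    extra <- setdiff(names(comp), aa)
    missing <- setdiff(aa, names(comp))
    stop("aa_composition must be named over exactly the 20 standard amino ",
         "acids",
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ",")),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ",")),
         call. = FALSE)
  }
  comp <- comp[aa]
  bad <- names(comp)[comp < 0 | !is.finite(comp)]
  if (length(bad) > 0L) {
    stop("aa_composition has negative or non-finite frequency for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(comp) - 1) > 1e-9) {
    stop(sprintf("aa_composition must sum to 1 (got %.12f)", sum(comp)),
         call. = FALSE)
  }
  comp
}

# composition for a given core length
composition_for_length <- function(design, len) {
  if (is.list(design$aa_composition) &&
      !is.null(names(design$aa_composition))) {
    comp <- design$aa_composition[[as.character(len)]]
    if (is.null(comp)) {
      stop("no composition configured for core length ", len, call. = FALSE)
    }
    comp
  } else {
    design$aa_composition
  }
}

# gene names as emitted by the simulators
emitted_gene <- function(name, allele_suffix) {
  if (allele_suffix) paste0(name, "*01") else name
}

#' @export
print.library_design <- function(x, ...) {
  cat("Randomized CDR3beta library design\n")
  cat("  CDR3beta form : ", x$flank_n, "<core>", x$flank_c, "\n", sep = "")
  cat("  core lengths  : ", paste(x$core_lengths, collapse = ", "), "\n",
      sep = "")
  cat("  V / J         : ", x$v_gene, " / ", x$j_gene, "\n", sep = "")
  invisible(x)
}
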