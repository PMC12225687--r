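#' The 20 standard amino acids
#'
#' Single-letter codes in the conventional BLOSUM ordering. All sequence
#' handling in the package is restricted to this alphabet; sequences with
#' other characters (X, B, Z, *, gaps) are filtered or rejected depending on
#' the operation.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Test whether sequences use only standard amino acids
#'
#' @param x character vector of amino-acid sequences.
#' @return Logical vector, `TRUE` where every residue of the sequence is one
#'   of the 20 standard amino acids and the sequence is non-empty.
#' @export
is_standard_aa <- function(x) {
  nzchar(x) & !is.na(x) & grepl("^[ARNDCQEGHILKMFPSTWYV]+$", x)
}

# split sequences into residue matrices / lists
split_residues <- function(x) strsplit(x, "", fixed = TRUE)

# residue matrix for equal-length sequences (n x L)
residue_matrix <- function(x) {
  if (length(x) == 0L) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  L <- unique(nchar(x))
  if (length(L) != 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  matrix(unlist(split_residues(x), use.names = FALSE),
         nrow = length(x), ncol = L, byrow = TRUE)
}

# per-position amino-acid frequency matrix (L x 20) from equal-length seqs
position_frequencies <- function(x, pseudocount = 0) {
  aa <- aa_alphabet()
  m <- residue_matrix(x)
  L <- ncol(m)
  out <- matrix(pseudocount, nrow = L, ncol = 20L,
                dimnames = list(NULL, aa))
  for (p in seq_len(L)) {
    tab <- table(factor(m[, p], levels = aa))
    out[p, ] <- out[p, ] + as.numeric(tab)
  }
  sweep(out, 1, rowSums(out), "/")
}
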