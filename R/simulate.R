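#' Configuration of a simulated phage screen
#'
#' Parameters of the synthetic input-library / panning-output pair. The
#' defaults are the conditions under which the package's recovery properties
#' are stated: a 10,000-clonotype input library, a 5,000-clonotype panned
#' output containing an even mixture of motif-drawn binders and
#' input-composition contaminants (`contamination = 0.5`), geometric clone
#' read counts with mean 3 (heavy-tailed clone sizes typical of selection
#' outputs), and a quarter of output clones forced to read count 1 as a
#' stand-in for sequencing-error singletons.
#'
#' @param n_input_clonotypes number of input-library draws (deduplicated by
#'   sequence, counts summed).
#' @param n_output_clonotypes number of unique output clonotypes.
#' @param contamination fraction of output clones drawn from the input
#'   composition instead of the planted motif, in `[0, 1]`.
#' @param count_model list with `name` (currently `"geometric"` or
#'   `"constant"`) and `mean`, the clone read-count distribution.
#' @param singleton_rate fraction of output clones whose count is forced
#'   to 1.
#' @param seed integer seed; all sampling is deterministic given it.
#'
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_input_clonotypes = 10000L,
                              n_output_clonotypes = 5000L,
                              contamination = 0.5,
                              count_model = list(name = "geometric", mean = 3),
                              singleton_rate = 0.25,
                              seed = 42L) {
  stopifnot(n_input_clonotypes >= 0, n_output_clonotypes >= 0,
            contamination >= 0, contamination <= 1,
            singleton_rate >= 0, singleton_rate <= 1)
  structure(
    list(n_input_clonotypes = as.integer(n_input_clonotypes),
         n_output_clonotypes = as.integer(n_output_clonotypes),
         contamination = contamination,
         count_model = count_model,
         singleton_rate = singleton_rate,
         seed = as.integer(seed)),
    class = "screen_sim_config"
  )
}

# draw clone read counts (all >= 1) from a count model
draw_counts <- function(n, count_model) {
  if (n == 0L) return(integer())
  name <- count_model$name %||% "geometric"
  switch(
    name,
    geometric = {
      mu <- count_model$mean %||% 3
      if (mu <= 1) return(rep(1L, n))
      1L + stats::rgeom(n, prob = 1 / (mu - 1 + 1))
    },
    constant = rep(as.integer(round(count_model$mean %||% 1)), n),
    stop("unknown count model: ", name, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() with safe handling of length-1 x (no 1:x expansion)
sample_from <- function(x, n, prob = NULL) {
  if (length(x) == 1L) return(rep(x, n))
  sample(x, n, replace = TRUE, prob = prob)
}

# sample n cores of length len i.i.d. from a composition vector
sample_cores <- function(n, len, comp) {
  if (n == 0L) return(character())
  aa <- names(comp)
  m <- matrix(sample(aa, n * len, replace = TRUE, prob = comp),
              nrow = n, ncol = len)
  apply(m, 1, paste, collapse = "")
}

new_clonotype_table <- function(cdr3_aa, count, v_call, j_call) {
  tibble::tibble(
    cdr3_aa = as.character(cdr3_aa),
    count = as.integer(count),
    v_call = as.character(v_call),
    j_call = as.character(j_call)
  )
}

#' Sample a randomized input phage library
#'
#' Draws `cfg$n_input_clonotypes` CDR3beta sequences of the form
#' `flank_n + core + flank_c`, with core lengths uniform over the design
#' lengths and residues i.i.d. from the design composition, then collapses
#' identical sequences to unique clonotypes with summed read counts.
#'
#' @param design a [library_design()].
#' @param cfg a [screen_sim_config()].
#' @return Clonotype tibble with columns `cdr3_aa`, `count`, `v_call`,
#'   `j_call`.
#' @export
sample_input_library <- function(design = library_design(),
                                 cfg = screen_sim_config()) {
  stopifnot(inherits(design, "library_design"))
  set.seed(cfg$seed)
  n <- cfg$n_input_clonotypes
  if (n == 0L) {
    return(new_clonotype_table(character(), integer(), character(),
                               character()))
  }
  lens <- sample_from(design$core_lengths, n)
  cores <- character(n)
  for (len in design$core_lengths) {
    idx <- which(lens == len)
    cores[idx] <- sample_cores(length(idx), len,
                               composition_for_length(design, len))
  }
  seqs <- paste0(design$flank_n, cores, design$flank_c)
  counts <- draw_counts(n, cfg$count_model)
  agg <- rowsum(counts, group = seqs)
  new_clonotype_table(
    cdr3_aa = rownames(agg),
    count = agg[, 1],
    v_call = emitted_gene(design$v_gene, design$allele_suffix),
    j_call = emitted_gene(design$j_gene, design$allele_suffix)
  )
}

#' A planted binding motif for panning simulation
#'
#' Bundles per-length position weight matrices (PWMs) with a selection
#' strength. During simulated panning a binder core of length L is drawn
#' position-wise with probability proportional to
#' `background(a)^(1-beta) * pwm[p, a]^beta` — a likelihood-ratio tilt of
#' the background toward the motif. `beta = 0` reproduces the background;
#' large `beta` concentrates on the motif consensus.
#'
#' @param pwm an L x 20 row-stochastic matrix (columns named by
#'   [aa_alphabet()]), or a named list of such matrices keyed by core
#'   length. Default: [default_planted_pwms()] for lengths 5, 7 and 9.
#' @param beta non-negative selection strength.
#' @param length_weights optional named numeric vector of sampling weights
#'   over motif lengths; defaults to uniform over the supplied PWMs.
#' @return A `planted_motif` object.
#' @export
planted_motif <- function(pwm = default_planted_pwms(), beta = 1,
                          length_weights = NULL) {
  stopifnot(beta >= 0)
  if (is.matrix(pwm)) {
    pwm <- stats::setNames(list(pwm), as.character(nrow(pwm)))
  }
  pwm <- lapply(pwm, validate_pwm)
  names(pwm) <- vapply(pwm, nrow, 0L)
  if (is.null(length_weights)) {
    length_weights <- stats::setNames(rep(1, length(pwm)) / length(pwm),
                                      names(pwm))
  }
  length_weights <- length_weights / sum(length_weights)
  structure(list(pwm = pwm, beta = beta, length_weights = length_weights),
            class = "planted_motif")
}

validate_pwm <- function(pwm) {
  aa <- aa_alphabet()
  if (is.null(colnames(pwm)) || !setequal(colnames(pwm), aa)) {
    stop("PWM columns must be named by the 20 standard amino acids",
         call. = FALSE)
  }
  pwm <- pwm[, aa, drop = FALSE]
  if (any(pwm < 0) || any(abs(rowSums(pwm) - 1) > 1e-9)) {
    stop("PWM rows must be non-negative and sum to 1", call. = FALSE)
  }
  pwm
}

#' Default planted PWM of one core length
#'
#' A motif with the qualitative features recovered from the NY-ESO-1
#' screens, shared across core lengths as the screens' per-length motifs
#' were: hydrophobic residues (Leu/Ile/Val) enriched at core position 2
#' and Gly enriched at position 3, milder preferences at positions 1 and
#' 4, and near-background tail positions. Built by mixing target residue
#' preferences into the supplied background so that low-weight positions
#' stay close to it.
#'
#' @param length core length (default 5).
#' @param background composition the motif is tilted away from; default
#'   [default_core_composition()].
#' @return A `length` x 20 row-stochastic matrix.
#' @export
default_planted_pwm <- function(length = 5L,
                                background = default_core_composition()) {
  stopifnot(length >= 4L)
  aa <- aa_alphabet()
  bg <- validate_composition(background)
  target <- function(...) {
    v <- stats::setNames(rep(0, 20L), aa)
    spec <- c(...)
    v[names(spec)] <- spec
    v / sum(v)
  }
  rows <- c(
    list(
      list(w = 0.70, t = target(N = 0.45, Y = 0.35, S = 0.1, G = 0.1)),
      list(w = 0.85, t = target(L = 0.45, I = 0.25, V = 0.2, T = 0.1)),
      list(w = 0.95, t = target(G = 0.95, A = 0.05)),
      list(w = 0.55, t = target(G = 0.4, N = 0.4, H = 0.2))
    ),
    rep(list(list(w = 0.30, t = target(T = 0.4, L = 0.3, N = 0.3))),
        length - 4L)
  )
  pwm <- t(vapply(rows, function(r) (1 - r$w) * bg + r$w * r$t,
                  numeric(20L)))
  colnames(pwm) <- aa
  pwm
}

#' Default planted motif PWMs for all design lengths
#'
#' One [default_planted_pwm()] per core length of the screen design
#' (5, 7 and 9 by default), mirroring screens in which binders are
#' recovered at every library length with a shared motif.
#'
#' @param lengths core lengths (default `c(5, 7, 9)`).
#' @param background composition passed to [default_planted_pwm()].
#' @return Named list of PWMs keyed by length.
#' @export
default_planted_pwms <- function(lengths = c(5L, 7L, 9L),
                                 background = default_core_composition()) {
  pwms <- lapply(lengths, default_planted_pwm, background = background)
  names(pwms) <- lengths
  pwms
}

# per-position tilted sampling distributions for one PWM, computed in
# the log domain so large beta cannot overflow
tilted_distributions <- function(pwm, background, beta) {
  lbg <- log(pmax(background, 1e-12))
  q <- t(vapply(seq_len(nrow(pwm)), function(p) {
    lw <- if (beta == 0) lbg else (1 - beta) * lbg + beta * log(pwm[p, ])
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(w)] <- 0
    w / sum(w)
  }, numeric(20L)))
  colnames(q) <- colnames(pwm)
  q
}

sample_motif_cores <- function(n, pwm, background, beta) {
  if (n == 0L) return(character())
  q <- tilted_distributions(pwm, background, beta)
  m <- vapply(seq_len(nrow(q)),
              function(p) sample(colnames(q), n, replace = TRUE,
                                 prob = q[p, ]),
              character(n))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  apply(m, 1, paste, collapse = "")
}

#' Simulate one round of phage panning
#'
#' Produces a panned output library from an input library and a planted
#' motif. Each output clonotype is, with probability
#' `1 - cfg$contamination`, a binder whose core is drawn from the
#' likelihood-ratio-tilted motif distribution (see [planted_motif()]), and
#' otherwise a contaminant resampled from the input composition. Output
#' clonotypes are unique; read counts are redrawn from the count model and
#' a `singleton_rate` fraction is forced to count 1. Ground-truth labels
#' are recorded per clonotype.
#'
#' @param input_table clonotype tibble from [sample_input_library()].
#' @param motif a [planted_motif()]; all motif lengths must be design
#'   lengths.
#' @param cfg a [screen_sim_config()].
#' @param design the [library_design()] the input was drawn from.
#' @return A `simulated_screen` object: list with `input_table`,
#'   `output_table`, `truth` (tibble `cdr3_aa`, `label`), `motif`,
#'   `design`, `cfg`.
#' @export
simulate_panning <- function(input_table, motif,
                             cfg = screen_sim_config(),
                             design = library_design()) {
  stopifnot(inherits(motif, "planted_motif"),
            inherits(design, "library_design"))
  if (nrow(input_table) == 0L) {
    stop("input_table is empty; nothing to pan", call. = FALSE)
  }
  motif_lens <- as.integer(names(motif$pwm))
  bad <- setdiff(motif_lens, design$core_lengths)
  if (length(bad) > 0L) {
    stop("motif core length(s) absent from library design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  n <- cfg$n_output_clonotypes

  # empirical core-length distribution of the input, for contaminants
  input_core_len <- nchar(input_table$cdr3_aa) -
    nchar(design$flank_n) - nchar(design$flank_c)
  len_tab <- table(factor(input_core_len, levels = design$core_lengths))
  len_prob <- as.numeric(len_tab) / sum(len_tab)

  draw_one_batch <- function(m) {
    is_binder <- stats::runif(m) >= cfg$contamination
    n_bind <- sum(is_binder)
    cores <- character(m)
    if (n_bind > 0L) {
      blen <- sample_from(motif_lens, n_bind,
                          prob = motif$length_weights)
      for (len in motif_lens) {
        idx <- which(is_binder)[blen == len]
        if (length(idx) > 0L) {
          cores[idx] <- sample_motif_cores(
            length(idx), motif$pwm[[as.character(len)]],
            composition_for_length(design, len), motif$beta)
        }
      }
    }
    if (m - n_bind > 0L) {
      clen <- sample_from(design$core_lengths, m - n_bind,
                          prob = len_prob)
      for (len in design$core_lengths) {
        idx <- which(!is_binder)[clen == len]
        if (length(idx) > 0L) {
          cores[idx] <- sample_cores(length(idx), len,
                                     composition_for_length(design, len))
        }
      }
    }
    list(seq = paste0(design$flank_n, cores, design$flank_c),
         label = ifelse(is_binder, "binder", "contaminant"))
  }

  # rejection-sample until n unique output clonotypes (or the sequence
  # space is effectively exhausted, e.g. a point-mass motif)
  seqs <- character(); labels <- character()
  stalls <- 0L
  while (length(seqs) < n && stalls < 60L) {
    need <- n - length(seqs)
    batch <- draw_one_batch(max(need, 16L))
    keep <- !duplicated(batch$seq) & !(batch$seq %in% seqs)
    if (!any(keep)) stalls <- stalls + 1L else stalls <- 0L
    take <- which(keep)[seq_len(min(need, sum(keep)))]
    seqs <- c(seqs, batch$seq[take])
    labels <- c(labels, batch$label[take])
  }

  counts <- draw_counts(length(seqs), cfg$count_model)
  n_single <- floor(cfg$singleton_rate * length(seqs))
  if (n_single > 0L) {
    counts[sample(length(seqs), n_single)] <- 1L
  }

  output <- new_clonotype_table(
    cdr3_aa = seqs, count = counts,
    v_call = emitted_gene(design$v_gene, design$allele_suffix),
    j_call = emitted_gene(design$j_gene, design$allele_suffix)
  )
  structure(
    list(input_table = input_table, output_table = output,
         truth = tibble::tibble(cdr3_aa = seqs, label = labels),
         motif = motif, design = design, cfg = cfg),
    class = "simulated_screen"
  )
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat("Simulated phage screen\n")
  cat("  input clonotypes : ", nrow(x$input_table), "\n", sep = "")
  cat("  output clonotypes: ", nrow(x$output_table), "\n", sep = "")
  cat("  truth binders    : ", sum(x$truth$label == "binder"), "\n", sep = "")
  invisible(x)
}

#' Configuration of a simulated TCR repertoire
#'
#' Emulates a repertoire extract restricted to one V/J pair (as when
#' querying a repertoire database for TRBV6-5 / TRBJ2-2 rearrangements),
#' with template-compatible flanks, a configurable core-length
#' distribution — including lengths outside the screen design, as real
#' repertoires contain — and optional spiked-in known binder sequences.
#'
#' @param n_records number of repertoire records.
#' @param core_length_distribution named numeric vector mapping core length
#'   to probability (sums to 1). Default spans lengths 3-10 with mass
#'   concentrated on 4-6, roughly the length profile of natural CDR3beta
#'   loops after removing the fixed flanks.
#' @param spike_in character vector of full CDR3beta sequences to plant,
#'   each inserted exactly once.
#' @param spike_positions optional record indices for the spike-ins
#'   (default: evenly spaced).
#' @param count_model read-count model, as in [screen_sim_config()].
#' @param seed integer seed.
#' @return A `repertoire_sim_config` list.
#' @export
repertoire_sim_config <- function(n_records = 30000L,
                                  core_length_distribution = c(
                                    "3" = 0.06, "4" = 0.22, "5" = 0.28,
                                    "6" = 0.20, "7" = 0.12, "8" = 0.07,
                                    "9" = 0.03, "10" = 0.02),
                                  spike_in = character(),
                                  spike_positions = NULL,
                                  count_model = list(name = "geometric",
                                                     mean = 2),
                                  seed = 42L) {
  stopifnot(n_records >= 0)
  if (abs(sum(core_length_distribution) - 1) > 1e-9) {
    stop("core_length_distribution must sum to 1", call. = FALSE)
  }
  structure(
    list(n_records = as.integer(n_records),
         core_length_distribution = core_length_distribution,
         spike_in = as.character(spike_in),
         spike_positions = spike_positions,
         count_model = count_model,
         seed = as.integer(seed)),
    class = "repertoire_sim_config"
  )
}

#' Generate a synthetic TCR repertoire table
#'
#' Emits AIRR-convention records (`junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`) with junctions `flank_n + core + flank_c`, core
#' lengths from the configured distribution and residues from the design
#' composition. Spike-in sequences are present exactly once each, at the
#' recorded indices; background draws colliding with a spike-in are
#' redrawn. A logical `is_spike_in` column records the truth.
#'
#' @param cfg a [repertoire_sim_config()].
#' @param design a [library_design()] supplying flanks, composition and
#'   V/J names.
#' @return Tibble with columns `junction_aa`, `v_call`, `j_call`,
#'   `duplicate_count`, `is_spike_in`.
#' @export
generate_repertoire <- function(cfg = repertoire_sim_config(),
                                design = library_design()) {
  stopifnot(inherits(cfg, "repertoire_sim_config"),
            inherits(design, "library_design"))
  spikes <- cfg$spike_in
  if (length(spikes) > 0L) {
    ok <- startsWith(spikes, design$flank_n) &
      endsWith(spikes, design$flank_c) & is_standard_aa(spikes) &
      nchar(spikes) > nchar(design$flank_n) + nchar(design$flank_c)
    if (!all(ok)) {
      stop("spike-in sequence(s) violate the flank convention: ",
           paste(spikes[!ok], collapse = ", "), call. = FALSE)
    }
  }
  set.seed(cfg$seed + 2L)
  n <- cfg$n_records
  if (n < length(spikes)) {
    stop("n_records smaller than the number of spike-ins", call. = FALSE)
  }
  n_bg <- n - length(spikes)

  lens <- as.integer(names(cfg$core_length_distribution))
  comp_for <- function(len) {
    if (is.list(design$aa_composition)) {
      design$aa_composition[[as.character(len)]] %||%
        design$aa_composition[[1L]]
    } else {
      design$aa_composition
    }
  }
  draw_bg <- function(m) {
    if (m == 0L) return(character())
    ls <- sample_from(lens, m, prob = cfg$core_length_distribution)
    cores <- character(m)
    for (len in unique(ls)) {
      idx <- which(ls == len)
      cores[idx] <- sample_cores(length(idx), len, comp_for(len))
    }
    paste0(design$flank_n, cores, design$flank_c)
  }
  bg <- draw_bg(n_bg)
  for (i in seq_len(20L)) {
    hit <- bg %in% spikes
    if (!any(hit)) break
    bg[hit] <- draw_bg(sum(hit))
  }

  if (is.null(cfg$spike_positions) && length(spikes) > 0L) {
    pos <- unique(round(seq(1L, n, length.out = length(spikes))))
    # guard against rounding collisions at small n
    while (length(pos) < length(spikes)) {
      pos <- sort(union(pos, sample(setdiff(seq_len(n), pos), 1L)))
    }
  } else {
    pos <- cfg$spike_positions
  }
  if (length(spikes) > 0L &&
      (length(pos) != length(spikes) || anyDuplicated(pos) ||
       any(pos < 1L | pos > n))) {
    stop("spike_positions must be distinct indices in 1..n_records",
         call. = FALSE)
  }

  junction <- character(n)
  is_spike <- logical(n)
  if (length(spikes) > 0L) {
    junction[pos] <- spikes
    is_spike[pos] <- TRUE
  }
  junction[!is_spike] <- bg

  tibble::tibble(
    junction_aa = junction,
    v_call = emitted_gene(design$v_gene, design$allele_suffix),
    j_call = emitted_gene(design$j_gene, design$allele_suffix),
    duplicate_count = draw_counts(n, cfg$count_model),
    is_spike_in = is_spike
  )
}
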