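#' Estimate background amino-acid frequencies from input-library cores
#'
#' Position-pooled residue frequencies of the (unselected) input library,
#' with additive smoothing so that every amino acid has strictly positive
#' probability. This is the frequency vector the mixture model's flat
#' component is fixed to: a sequence drawn from it has likelihood
#' `prod_p b(s_p)` irrespective of position.
#'
#' @param input_cores a `core_set` from [extract_cores()], or a character
#'   vector of core sequences (lengths may differ; residues are pooled).
#' @param pseudocount additive smoothing count per amino acid
#'   (default 0.5). With `pseudocount = 0` the raw empirical frequencies
#'   are returned (possibly containing zeros).
#' @return Named numeric frequency vector over [aa_alphabet()], summing
#'   to 1.
#' @export
estimate_background <- function(input_cores, pseudocount = 0.5) {
  if (inherits(input_cores, "core_set")) {
    input_cores <- unlist(lapply(input_cores, `[[`, "core"),
                          use.names = FALSE)
  }
  if (length(input_cores) == 0L) {
    stop("cannot estimate background from an empty input library",
         call. = FALSE)
  }
  if (!all(is_standard_aa(input_cores))) {
    stop("input cores contain non-standard amino acids", call. = FALSE)
  }
  residues <- unlist(split_residues(input_cores), use.names = FALSE)
  counts <- table(factor(residues, levels = aa_alphabet()))
  freqs <- as.numeric(counts) + pseudocount
  stats::setNames(freqs / sum(freqs), aa_alphabet())
}

# encode equal-length cores as an n x L integer matrix over aa indices
encode_cores <- function(cores) {
  aa <- aa_alphabet()
  m <- residue_matrix(cores)
  idx <- matrix(match(m, aa), nrow = nrow(m), ncol = ncol(m))
  if (anyNA(idx)) {
    stop("cores contain non-standard amino acids", call. = FALSE)
  }
  idx
}

# per-sequence log-likelihood under a PWM (or a flat freq vector)
pwm_loglik <- function(idx, pwm) {
  L <- ncol(idx)
  lp <- log(pwm)
  ll <- numeric(nrow(idx))
  for (p in seq_len(L)) {
    ll <- ll + lp[p, idx[, p]]
  }
  ll
}

#' Fit a mixture of PWM motifs over a fixed flat background
#'
#' Deconvolves a set of equal-length core sequences into `k` position
#' weight matrix (PWM) motif components plus one flat component whose
#' per-position frequencies are fixed to the background (input-library)
#' composition and never updated. The per-sequence likelihood is
#' `w_flat * prod_p b(s_p) + sum_m w_m * prod_p f_mp(s_p)`, maximized by
#' EM with multiple random restarts; the best-likelihood fit is kept.
#'
#' @param cores character vector of core sequences, all the same length.
#' @param k number of motif components (>= 1; default 1).
#' @param background named frequency vector from [estimate_background()].
#' @param pseudocount additive pseudocount on PWM rows in the M-step
#'   (default 0.1).
#' @param tol relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param n_restarts number of random initializations (default 5).
#' @param seed integer seed for the restarts.
#' @return A `pwm_mixture` object: list with `pwm` (list of k L x 20
#'   matrices), `background`, `weights` (named, flat component first),
#'   `responsibilities` (n x (k+1), column 1 = flat), `loglik`, `trace`
#'   (per-iteration log-likelihoods of the winning restart), `n_iter`,
#'   `converged`.
#' @export
fit_mixture <- function(cores, k = 1L, background,
                        pseudocount = 0.1, tol = 1e-6,
                        max_iter = 500L, n_restarts = 5L, seed = 1L) {
  stopifnot(k >= 1L, pseudocount >= 0)
  background <- background[aa_alphabet()]
  if (anyNA(background) || any(background <= 0)) {
    stop("background must be strictly positive over the 20 amino acids",
         call. = FALSE)
  }
  n <- length(cores)
  if (n < k + 1L) {
    stop(sprintf("need at least %d sequences to fit %d motif(s) + flat",
                 k + 1L, k), call. = FALSE)
  }
  idx <- encode_cores(cores)
  L <- ncol(idx)
  ll_flat <- pwm_loglik(idx, matrix(background, nrow = L, ncol = 20L,
                                    byrow = TRUE,
                                    dimnames = list(NULL, aa_alphabet())))

  m_step_pwm <- function(resp_m) {
    # responsibility-weighted per-position counts + pseudocount
    pwm <- matrix(pseudocount, nrow = L, ncol = 20L,
                  dimnames = list(NULL, aa_alphabet()))
    for (p in seq_len(L)) {
      acc <- rowsum(resp_m, group = idx[, p])
      pwm[p, as.integer(rownames(acc))] <-
        pwm[p, as.integer(rownames(acc))] + acc[, 1]
    }
    sweep(pwm, 1, rowSums(pwm), "/")
  }

  run_em <- function() {
    # random soft initialization of responsibilities
    resp <- matrix(stats::runif(n * (k + 1L), 0.25, 1), nrow = n)
    resp <- sweep(resp, 1, rowSums(resp), "/")
    weights <- colMeans(resp)
    pwms <- lapply(seq_len(k), function(m) m_step_pwm(resp[, m + 1L]))
    trace <- numeric()
    loglik <- -Inf
    for (iter in seq_len(max_iter)) {
      # E-step in log domain
      comp_ll <- cbind(ll_flat,
                       vapply(pwms, function(pwm) pwm_loglik(idx, pwm),
                              numeric(n)))
      comp_ll <- sweep(comp_ll, 2, log(weights), "+")
      mx <- apply(comp_ll, 1, max)
      lse <- mx + log(rowSums(exp(comp_ll - mx)))
      new_loglik <- sum(lse)
      resp <- exp(comp_ll - lse)
      trace <- c(trace, new_loglik)
      converged <- iter > 1L &&
        (new_loglik - loglik) < tol * abs(loglik)
      loglik <- new_loglik
      # M-step: weights for all components, PWMs for motifs only
      weights <- colMeans(resp)
      weights <- pmax(weights, 1e-12)
      weights <- weights / sum(weights)
      pwms <- lapply(seq_len(k), function(m) m_step_pwm(resp[, m + 1L]))
      if (converged) break
    }
    list(pwm = pwms, weights = weights, responsibilities = resp,
         loglik = loglik, trace = trace, n_iter = length(trace),
         converged = converged)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_em()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  names(best$weights) <- c("flat", paste0("motif", seq_len(k)))
  colnames(best$responsibilities) <- names(best$weights)
  best$background <- background
  best$k <- k
  best$cores <- cores
  class(best) <- "pwm_mixture"
  best
}

#' @export
print.pwm_mixture <- function(x, ...) {
  cat("PWM mixture (", x$k, " motif(s) + fixed flat background)\n",
      sep = "")
  cat("  n sequences :", nrow(x$responsibilities), "\n")
  cat("  weights     :",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights),
            collapse = ", "), "\n")
  cat("  log-lik     :", format(x$loglik), "(", x$n_iter, "iterations,",
      if (x$converged) "converged" else "max_iter reached", ")\n")
  invisible(x)
}

#' Per-position information content of a motif
#'
#' Kullback-Leibler divergence of each PWM row from the background, in
#' bits: `IC_p = sum_a f_pa * log2(f_pa / b_a)`. Relative to a flat
#' (background) motif this is zero; a point mass on a residue with
#' background probability `b` gives `log2(1/b)` bits. Non-negative up to
#' floating error whenever the row is a probability vector.
#'
#' @param pwm L x 20 row-stochastic matrix.
#' @param background strictly positive named frequency vector.
#' @return Numeric vector of L information contents (bits).
#' @export
position_information_content <- function(pwm, background) {
  pwm <- validate_pwm(pwm)
  background <- background[colnames(pwm)]
  if (anyNA(background) || any(background <= 0)) {
    stop("background has zero or missing entries; smooth it first",
         call. = FALSE)
  }
  apply(pwm, 1, function(f) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / background[nz]))
  })
}

#' Split cores into motif binders and background contaminants
#'
#' Assigns each core to its maximum-responsibility mixture component
#' (ties go to the flat component — the conservative choice). Cores in the
#' flat component, or in any motif whose maximum per-position information
#' content does not exceed `ic_threshold`, are labeled putative
#' contaminants; the rest are binders.
#'
#' @param model a fitted [fit_mixture()] model.
#' @param cores the core sequences the model was fitted on (default: the
#'   ones stored in the model).
#' @param ic_threshold information-content gate in bits (default 1.0; a
#'   motif must have at least one position strictly above it).
#' @return A `deconvolution_result`: list with `binders`, `contaminants`
#'   (character vectors partitioning the cores), `assignment` (component
#'   per core), `pwm` (motif PWMs), `ic` (per-motif IC vectors),
#'   `ic_pass` (per-motif logical), `weights`.
#' @export
classify_binders <- function(model, cores = model$cores,
                             ic_threshold = 1.0) {
  stopifnot(inherits(model, "pwm_mixture"))
  resp <- model$responsibilities
  stopifnot(length(cores) == nrow(resp))
  ic <- lapply(model$pwm, position_information_content,
               background = model$background)
  ic_pass <- vapply(ic, function(v) max(v) > ic_threshold, logical(1))

  # max responsibility; exact ties resolved to the flat component, which
  # is column 1, so which.max's first-index rule is the conservative one
  assign_idx <- apply(resp, 1, which.max)
  component <- colnames(resp)[assign_idx]
  motif_ok <- c(FALSE, ic_pass)  # flat never passes
  is_binder <- motif_ok[assign_idx]

  structure(
    list(binders = cores[is_binder],
         contaminants = cores[!is_binder],
         assignment = component,
         pwm = model$pwm,
         ic = ic,
         ic_pass = ic_pass,
         weights = model$weights),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("Motif deconvolution result\n")
  cat("  binders     :", length(x$binders), "\n")
  cat("  contaminants:", length(x$contaminants), "\n")
  cat("  motif IC gate:",
      paste(ifelse(x$ic_pass, "pass", "fail"), collapse = ", "), "\n")
  invisible(x)
}

#' Deconvolve a screen's cores length by length
#'
#' Runs [fit_mixture()] + [classify_binders()] independently for each core
#' length of a screen output (fixed-length PWMs need no alignment), with
#' the background estimated from the input library.
#'
#' @param output_cores `core_set` of the panned output.
#' @param input_cores `core_set` of the input library (background source).
#' @param k motifs per length (default 1).
#' @param ic_threshold information-content gate in bits.
#' @param min_sequences lengths with fewer cores than this are labeled
#'   all-contaminant without fitting (default `k + 2`).
#' @param ... passed to [fit_mixture()].
#' @return Named list (by length) of `deconvolution_result`s, with the
#'   shared `background` attached as an attribute.
#' @export
deconvolve_cores <- function(output_cores, input_cores, k = 1L,
                             ic_threshold = 1.0,
                             min_sequences = k + 2L, ...) {
  background <- estimate_background(input_cores)
  results <- lapply(names(output_cores), function(len) {
    cores <- output_cores[[len]]$core
    if (length(cores) < min_sequences) {
      return(structure(
        list(binders = character(), contaminants = cores,
             assignment = rep("flat", length(cores)),
             pwm = list(), ic = list(), ic_pass = logical(),
             weights = c(flat = 1)),
        class = "deconvolution_result"))
    }
    model <- fit_mixture(cores, k = k, background = background, ...)
    classify_binders(model, cores, ic_threshold = ic_threshold)
  })
  names(results) <- names(output_cores)
  attr(results, "background") <- background
  results
}
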