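#' Default end-to-end pipeline configuration
#'
#' Nested list of per-stage parameter blocks consumed by
#' [run_pipeline()]. Every entry can be overridden by supplying a
#' partial list (or a YAML file) whose fields replace the defaults
#' recursively; the global `seed` offsets every stage-level seed so one
#' integer reproduces a whole run.
#'
#' @param seed global integer seed.
#' @param output_dir directory for stage outputs and the manifest.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42L,
                                    output_dir = tempfile("phagetcr_run")) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    design = list(),             # overrides for library_design()
    screen = list(               # overrides for screen_sim_config()
      n_input_clonotypes = 10000L,
      n_output_clonotypes = 5000L,
      contamination = 0.5
    ),
    motif = list(beta = 1),      # overrides for planted_motif()
    template_core = "YVGNT",
    deconvolution = list(k = 1L, ic_threshold = 1.0),
    classifier = list(           # overrides for classifier_config()
      embedding_dim = 32L, n_heads = 4L, n_layers = 1L, ff_dim = 64L,
      max_epochs = 25L, patience = 5L
    ),
    cv = list(n_folds = 5L),
    repertoire = list(           # overrides for repertoire_sim_config()
      n_records = 20000L,
      n_spike_in = 25L
    ),
    mine = list(n_candidates = 30L, strategy = "broad_range"),
    benchmark = list(n_eval = 200L),
    xreact = list(               # proteome scan on a synthetic proteome
      n_proteins = 40L,
      plant = c("FLTLWLTQV", "GLRMWIKQV", "TQIQWATQV"),
      top_n = 25L
    )
  )
}

# recursive override of defaults by user-supplied fields
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

call_with <- function(fn, overrides, ...) {
  do.call(fn, c(list(...), overrides))
}

#' Run the end-to-end synthetic screen workflow
#'
#' Executes the pipeline stages in dependency order on synthetic data:
#' `simulate` (input library, panned output, repertoire with spiked-in
#' planted binders), `process` (quality filters + core extraction),
#' `deconvolve` (per-length PWM mixture vs flat background), `train`
#' (classifier on deconvolved binders vs input-only negatives), `cv`
#' (stratified fivefold cross-validation), `mine` (filter/score/rank the
#' repertoire, select candidates), `benchmark` (AUC of the classifier
#' and the similarity baselines on held-out truth-labeled clones) and
#' `xreact` (proteome scan for epitope-like self-peptides). Writes
#' stage outputs as TSV under `config$output_dir` plus a JSON manifest
#' recording seeds, per-stage summaries and output files. Reruns with an
#' identical config reproduce the manifest except for its timestamp.
#'
#' @param config partial override list (see
#'   [default_pipeline_config()]), or a path to a YAML file of the same
#'   shape.
#' @param stages character vector of stages to run (default all, in
#'   order; prerequisites of a requested stage are run automatically).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "process", "deconvolve",
                                    "train", "cv", "mine", "benchmark",
                                    "xreact")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  all_stages <- c("simulate", "process", "deconvolve", "train", "cv",
                  "mine", "benchmark", "xreact")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # running a stage requires everything before it except the optional tails
  need_through <- max(match(stages, all_stages))
  run <- all_stages[seq_len(need_through)]
  run <- union(setdiff(run, c("cv", "benchmark", "xreact")),
               intersect(stages, c("cv", "benchmark", "xreact")))

  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_file <- function(name) file.path(cfg$output_dir, name)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phagetcr")),
    seed = cfg$seed,
    stages = run,
    outputs = list(),
    summary = list()
  )
  stage_failed <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  design <- call_with(library_design, cfg$design)
  screen_cfg <- call_with(screen_sim_config, cfg$screen,
                          seed = cfg$seed)
  motif <- call_with(planted_motif, cfg$motif)

  ## simulate ----------------------------------------------------------
  state <- tryCatch({
    input <- sample_input_library(design, screen_cfg)
    screen <- simulate_panning(input, motif, screen_cfg, design)
    write_clonotype_table(input, out_file("input_library.tsv"), "mixcr")
    write_clonotype_table(screen$output_table,
                          out_file("panned_output.tsv"), "mixcr")
    write_truth_sidecar(screen, out_file("panned_truth.tsv"))
    list(input = input, screen = screen)
  }, error = function(e) stage_failed("simulate", e))
  manifest$outputs$simulate <- c("input_library.tsv", "panned_output.tsv",
                                 "panned_truth.tsv")
  manifest$summary$simulate <- list(
    n_input = nrow(state$input),
    n_output = nrow(state$screen$output_table),
    n_truth_binders = sum(state$screen$truth$label == "binder")
  )

  ## process -----------------------------------------------------------
  proc <- tryCatch({
    input_filt <- filter_clonotypes(state$input, cfg$template_core,
                                    design)
    output_filt <- filter_clonotypes(state$screen$output_table,
                                     cfg$template_core, design)
    input_cores <- extract_cores(input_filt, design)
    output_cores <- extract_cores(output_filt, design)
    readr::write_tsv(core_set_table(output_cores),
                     out_file("output_cores.tsv"), progress = FALSE)
    list(input_cores = input_cores, output_cores = output_cores,
         audit = list(input = attr(input_filt, "audit"),
                      output = attr(output_filt, "audit")))
  }, error = function(e) stage_failed("process", e))
  manifest$outputs$process <- "output_cores.tsv"
  manifest$summary$process <- lapply(proc$audit, as.list)

  ## deconvolve --------------------------------------------------------
  dec <- tryCatch({
    res <- call_with(deconvolve_cores, cfg$deconvolution,
                     output_cores = proc$output_cores,
                     input_cores = proc$input_cores,
                     seed = cfg$seed + 10L)
    binder_cdr3 <- paste0(design$flank_n,
                          unlist(lapply(res, `[[`, "binders"),
                                 use.names = FALSE),
                          design$flank_c)
    readr::write_tsv(tibble::tibble(cdr3_aa = binder_cdr3),
                     out_file("deconvolved_binders.tsv"),
                     progress = FALSE)
    list(results = res, binder_cdr3 = binder_cdr3)
  }, error = function(e) stage_failed("deconvolve", e))
  manifest$outputs$deconvolve <- "deconvolved_binders.tsv"
  manifest$summary$deconvolve <- list(
    n_binders = length(dec$binder_cdr3),
    ic_pass = lapply(dec$results, function(r) unname(r$ic_pass))
  )

  ## train -------------------------------------------------------------
  clf_cfg <- call_with(classifier_config, cfg$classifier,
                       seed = cfg$seed + 20L)
  trained <- tryCatch({
    negatives <- setdiff(state$input$cdr3_aa,
                         state$screen$output_table$cdr3_aa)
    fit <- train_classifier(dec$binder_cdr3, negatives, clf_cfg)
    list(fit = fit, negatives = negatives)
  }, error = function(e) stage_failed("train", e))
  manifest$summary$train <- list(
    n_pos = trained$fit$history$n_pos,
    n_neg = trained$fit$history$n_neg,
    epochs = length(trained$fit$history$train_loss),
    best_epoch = trained$fit$history$best_epoch
  )

  ## cv ----------------------------------------------------------------
  if ("cv" %in% run) {
    cv <- tryCatch(
      crossvalidate(dec$binder_cdr3, trained$negatives,
                    n_folds = cfg$cv$n_folds, config = clf_cfg),
      error = function(e) stage_failed("cv", e))
    readr::write_tsv(
      tibble::tibble(fold = seq_along(cv$fold_auc), auc = cv$fold_auc),
      out_file("cv_auc.tsv"), progress = FALSE)
    manifest$outputs$cv <- "cv_auc.tsv"
    manifest$summary$cv <- list(fold_auc = cv$fold_auc,
                                mean_auc = cv$mean_auc)
  }

  ## mine --------------------------------------------------------------
  mined <- tryCatch({
    set.seed(cfg$seed + 29L)
    n_spike <- min(cfg$repertoire$n_spike_in, length(dec$binder_cdr3))
    spikes <- sample(dec$binder_cdr3, n_spike)
    rep_cfg <- call_with(
      repertoire_sim_config,
      cfg$repertoire[setdiff(names(cfg$repertoire), "n_spike_in")],
      spike_in = spikes, seed = cfg$seed + 30L)
    rep_tab <- generate_repertoire(rep_cfg, design)
    filtered <- filter_repertoire(rep_tab, design)
    scored <- rank_repertoire(trained$fit, filtered)
    cand <- select_candidates(scored, cfg$mine$n_candidates,
                              strategy = cfg$mine$strategy,
                              seed = cfg$seed + 31L)
    readr::write_tsv(
      scored[, c("junction_aa", "v_call", "j_call", "score", "rank",
                 "core_length")],
      out_file("scored_repertoire.tsv"), progress = FALSE)
    readr::write_tsv(
      cand[, c("junction_aa", "v_call", "j_call", "score", "rank",
               "core_length")],
      out_file("candidates.tsv"), progress = FALSE)
    list(repertoire = rep_tab, scored = scored, candidates = cand,
         spikes = spikes)
  }, error = function(e) stage_failed("mine", e))
  spike_ranks <- mined$scored$rank[mined$scored$junction_aa %in%
                                     mined$spikes]
  manifest$outputs$mine <- c("scored_repertoire.tsv", "candidates.tsv")
  manifest$summary$mine <- list(
    n_repertoire = nrow(mined$repertoire),
    n_scored = nrow(mined$scored),
    n_candidates = nrow(mined$candidates),
    spike_in_top1pct = mean(spike_ranks <=
                              ceiling(0.01 * nrow(mined$scored))),
    n_planted_in_top10 = sum(mined$scored$junction_aa[1:10] %in%
                               mined$spikes)
  )

  ## benchmark ---------------------------------------------------------
  if ("benchmark" %in% run) {
    bench <- tryCatch({
      # synthetic analogue of the tested-candidate benchmark: planted
      # binders found in the repertoire vs background repertoire records
      set.seed(cfg$seed + 40L)
      is_spike <- mined$scored$junction_aa %in% mined$spikes
      bg_pool <- mined$scored$junction_aa[!is_spike]
      n_neg <- min(cfg$benchmark$n_eval, length(bg_pool))
      labeled <- tibble::tibble(
        cdr3_aa = c(mined$scored$junction_aa[is_spike],
                    sample(bg_pool, n_neg)),
        label = c(rep(1L, sum(is_spike)), rep(0L, n_neg)))
      reference <- paste0(design$flank_n, cfg$template_core,
                          design$flank_c)
      output_set <- state$screen$output_table$cdr3_aa
      fit <- trained$fit
      benchmark_methods(labeled, list(
        classifier = function(s) score_sequences(fit, s),
        exact_match = function(s) exact_match_score(s, output_set),
        blosum_similarity = function(s)
          blosum_similarity(s, reference, design = design),
        cdr3_distance = list(
          score = function(s) cdr3_distance(s, reference,
                                            design = design),
          type = "distance")
      ))
    }, error = function(e) stage_failed("benchmark", e))
    readr::write_tsv(bench, out_file("benchmark_auc.tsv"),
                     progress = FALSE)
    manifest$outputs$benchmark <- "benchmark_auc.tsv"
    manifest$summary$benchmark <- stats::setNames(
      as.list(bench$auc), bench$method)
  }

  ## xreact ------------------------------------------------------------
  if ("xreact" %in% run) {
    xr <- tryCatch({
      prot <- synthetic_proteome(n_proteins = cfg$xreact$n_proteins,
                                 plant = cfg$xreact$plant,
                                 seed = cfg$seed + 50L)
      sc_cfg <- scan_config(rank_source = list(mode = "heuristic"))
      cands <- filter_binders(enumerate_peptides(prot), sc_cfg)
      rank_candidates(cands, top_n = cfg$xreact$top_n, cfg = sc_cfg)
    }, error = function(e) stage_failed("xreact", e))
    readr::write_tsv(xr, out_file("xreact_candidates.tsv"),
                     progress = FALSE)
    manifest$outputs$xreact <- "xreact_candidates.tsv"
    manifest$summary$xreact <- list(
      n_candidates = nrow(xr),
      top_peptide = if (nrow(xr) > 0L) xr$peptide[1] else NA_character_,
      top_similarity = if (nrow(xr) > 0L) xr$similarity[1] else NA_real_
    )
  }

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
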