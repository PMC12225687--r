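# shared fixtures and small utilities for the suite

# a single-length design keeps EM and classifier fixtures fast
design5 <- function() library_design(core_lengths = 5L)

# composition concentrated on one residue (degenerate corner cases)
point_mass_composition <- function(aa = "G") {
  comp <- stats::setNames(rep(0, 20), aa_alphabet())
  comp[aa] <- 1
  comp
}

# small screen for filter/deconvolution tests
tiny_screen <- function(n_input = 2000L, n_output = 1500L, seed = 11L,
                        contamination = 0.5, beta = 1,
                        design = design5(),
                        pwm = default_planted_pwm(5L)) {
  cfg <- screen_sim_config(n_input_clonotypes = n_input,
                           n_output_clonotypes = n_output,
                           contamination = contamination, seed = seed)
  input <- sample_input_library(design, cfg)
  screen <- simulate_panning(input, planted_motif(pwm, beta = beta),
                             cfg, design)
  screen
}

# classifier config small enough for unit tests
tiny_clf_config <- function(...) {
  defaults <- list(embedding_dim = 16L, n_heads = 2L, n_layers = 1L,
                   ff_dim = 32L, dropout = 0.1, max_epochs = 6L,
                   patience = 3L, batch_size = 32L, seed = 101L)
  do.call(classifier_config, utils::modifyList(defaults, list(...)))
}

# sequences separable by one rule: positives carry G at core position 3
separable_sets <- function(n_per_class, seed = 5L,
                           comp = default_core_composition()) {
  set.seed(seed)
  non_g <- setdiff(names(comp)[comp > 0], "G")
  draw <- function(n, with_g) {
    cores <- replicate(n, paste(sample(names(comp), 5, replace = TRUE,
                                       prob = comp), collapse = ""))
    third <- if (with_g) "G" else sample(non_g, n, replace = TRUE)
    substr(cores, 3, 3) <- third
    unique(paste0("CASS", cores, "GELFF"))
  }
  pos <- draw(n_per_class, TRUE)
  neg <- draw(n_per_class, FALSE)
  list(positives = pos, negatives = setdiff(neg, pos))
}

# exhaustive pairwise AUC oracle (ties count 1/2)
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# parameter-tree helpers for the finite-difference gradient check
flat_param_paths <- function(tree, prefix = list()) {
  if (is.list(tree)) {
    out <- list()
    for (i in seq_along(tree)) {
      key <- if (!is.null(names(tree)) && nzchar(names(tree)[i])) {
        names(tree)[i]
      } else {
        i
      }
      out <- c(out, flat_param_paths(tree[[i]], c(prefix, list(key))))
    }
    out
  } else {
    list(list(path = prefix, len = length(tree)))
  }
}

get_leaf <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

set_leaf <- function(tree, path, val) {
  if (length(path) == 1L) {
    tree[[path[[1]]]] <- val
    return(tree)
  }
  tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
  tree
}

# total variation distance between two discrete distributions
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
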