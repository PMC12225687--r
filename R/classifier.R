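#' Classifier configuration
#'
#' Hyperparameters of the CDR3beta transformer-encoder classifier.
#' Defaults are sized for short sequences and screen-scale training sets
#' (hundreds to tens of thousands of positives): embedding 64, 2 encoder
#' layers with 4 attention heads, feed-forward width 128, dropout 0.1,
#' Adam at learning rate 1e-3, batches of 128, up to 100 epochs with
#' early stopping (patience 10) on a held-out split, and a 1:1
#' negative:positive sampling ratio.
#'
#' @param embedding_dim embedding width (heads must divide it).
#' @param n_heads attention heads per layer.
#' @param n_layers encoder layers.
#' @param ff_dim feed-forward hidden width.
#' @param dropout dropout probability during training.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param neg_ratio negatives sampled per positive (negatives beyond
#'   `neg_ratio * n_positives` are subsampled).
#' @param val_fraction fraction of training data held out for early
#'   stopping.
#' @param max_len maximum sequence length in residues.
#' @param seed integer seed governing initialization, sampling and
#'   shuffling.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(embedding_dim = 64L, n_heads = 4L,
                              n_layers = 2L, ff_dim = 128L,
                              dropout = 0.1, lr = 1e-3,
                              batch_size = 128L, max_epochs = 100L,
                              patience = 10L, neg_ratio = 1,
                              val_fraction = 0.1, max_len = 24L,
                              seed = 1L) {
  stopifnot(embedding_dim %% n_heads == 0L,
            embedding_dim > 0L, n_heads > 0L, n_layers > 0L, ff_dim > 0L,
            dropout >= 0, dropout < 1, lr > 0, batch_size > 0L,
            max_epochs > 0L, patience > 0L, neg_ratio > 0,
            val_fraction > 0, val_fraction < 1, max_len > 0L)
  structure(
    list(embedding_dim = as.integer(embedding_dim),
         n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
         ff_dim = as.integer(ff_dim), dropout = dropout, lr = lr,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), neg_ratio = neg_ratio,
         val_fraction = val_fraction, max_len = as.integer(max_len),
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Train the CDR3beta binding classifier
#'
#' Trains the transformer-encoder scorer on screen-derived binders
#' (positives) versus input-library sequences absent from the screen
#' output (negatives). The two sets must be disjoint — by construction the
#' negative set excludes anything observed in the output, so an overlap
#' indicates an upstream bookkeeping error and is rejected. Training
#' minimizes binary cross-entropy with Adam; a stratified split of
#' `val_fraction` is held out and training stops when its loss has not
#' improved for `patience` epochs, restoring the best weights. Fully
#' deterministic given `config$seed`.
#'
#' @param positives,negatives character vectors of full CDR3beta
#'   sequences.
#' @param config a [classifier_config()].
#' @return A `tcr_classifier`: list with `params`, `vocab`, `config` and
#'   `history` (per-epoch train/validation losses, best epoch).
#' @export
train_classifier <- function(positives, negatives,
                             config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both positive and negative sets must be non-empty",
         call. = FALSE)
  }
  overlap <- intersect(positives, negatives)
  if (length(overlap) > 0L) {
    stop("positive and negative sets overlap (negatives must be input ",
         "sequences absent from the screen output); e.g. ",
         paste(utils::head(overlap, 3L), collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  n_neg_wanted <- ceiling(config$neg_ratio * length(positives))
  if (length(negatives) > n_neg_wanted) {
    negatives <- sample(negatives, n_neg_wanted)
  }
  seqs <- c(positives, negatives)
  y <- c(rep(1, length(positives)), rep(0, length(negatives)))

  vocab <- token_vocab(config$max_len)
  enc <- encode_sequences(seqs, vocab)

  # stratified validation split
  val_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
    n_val <- max(1L, floor(config$val_fraction * length(idx)))
    sample(idx, n_val)
  }), use.names = FALSE)
  train_idx <- setdiff(seq_along(y), val_idx)

  params <- init_params(config, vocab)
  state <- adam_init(params)
  history <- list(train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)

  eval_loss <- function(p, idx) {
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 256L))) {
      fw <- transformer_forward(p, enc$tokens[chunk, , drop = FALSE],
                                enc$mask[chunk, , drop = FALSE], config)
      tot <- tot + bce_with_logits(fw$logits, y[chunk])$loss *
        length(chunk)
    }
    tot / length(idx)
  }

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(train_idx)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      fw <- transformer_forward(params, enc$tokens[b, , drop = FALSE],
                                enc$mask[b, , drop = FALSE], config,
                                dropout_p = config$dropout,
                                keep_cache = TRUE)
      l <- bce_with_logits(fw$logits, y[b])
      grads <- transformer_backward(params, fw$cache, l$dlogits, config)
      st <- adam_step(params, grads, state, config$lr)
      params <- st$params
      state <- st$state
      epoch_loss <- epoch_loss + l$loss * length(b)
    }
    vl <- eval_loss(params, val_idx)
    history$train_loss <- c(history$train_loss,
                            epoch_loss / length(train_idx))
    history$val_loss <- c(history$val_loss, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  history$best_epoch <- best$epoch
  history$n_pos <- length(positives)
  history$n_neg <- length(negatives)

  structure(
    list(params = best$params, vocab = vocab, config = config,
         history = history),
    class = "tcr_classifier"
  )
}

#' @export
print.tcr_classifier <- function(x, ...) {
  cat("CDR3beta transformer classifier\n")
  cat("  trained on ", x$history$n_pos, " positives / ",
      x$history$n_neg, " negatives\n", sep = "")
  cat("  epochs run : ", length(x$history$train_loss),
      " (best validation at epoch ", x$history$best_epoch, ")\n",
      sep = "")
  invisible(x)
}

#' Score sequences with a trained classifier
#'
#' Returns the model's pre-sigmoid output — a log-odds-scale binding
#' score, one finite real per sequence. Scores are computed per sequence,
#' so batch composition and ordering cannot change them; lengths may
#' differ from those seen in training (up to `max_len`).
#'
#' @param model a [train_classifier()] model.
#' @param seqs character vector of CDR3beta sequences.
#' @return Numeric vector of scores, one per sequence.
#' @export
score_sequences <- function(model, seqs) {
  stopifnot(inherits(model, "tcr_classifier"))
  if (length(seqs) == 0L) return(numeric())
  enc <- encode_sequences(as.character(seqs), model$vocab)
  out <- numeric(length(seqs))
  for (chunk in split(seq_along(seqs),
                      ceiling(seq_along(seqs) / 256L))) {
    fw <- transformer_forward(model$params,
                              enc$tokens[chunk, , drop = FALSE],
                              enc$mask[chunk, , drop = FALSE],
                              model$config)
    out[chunk] <- fw$logits
  }
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' scores above a random negative, with ties counted 0.5. Equal to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores numeric scores (larger = more positive-like).
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve points (FPR, TPR) at every threshold
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  tibble::tibble(fpr = c(0, fp / max(fp[length(fp)], 1L)),
                 tpr = c(0, tp / max(tp[length(tp)], 1L)))
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits positives and negatives into `n_folds` stratified folds, trains
#' on each complement and scores the held-out fold. Fold assignment is
#' derived from `config$seed`; folds partition the data with no leakage.
#'
#' @param positives,negatives character vectors of sequences.
#' @param n_folds number of folds (default 5).
#' @param config a [classifier_config()].
#' @return A `cv_report`: list with `fold_auc`, `mean_auc`, `roc`
#'   (per-fold ROC point tibbles), `folds` (per-sequence fold ids,
#'   list of `positives` and `negatives`).
#' @export
crossvalidate <- function(positives, negatives, n_folds = 5L,
                          config = classifier_config()) {
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) < n_folds || length(negatives) < n_folds) {
    stop("each class needs at least n_folds sequences", call. = FALSE)
  }
  set.seed(config$seed)
  fold_of <- function(n) sample(rep_len(seq_len(n_folds), n))
  fp <- fold_of(length(positives))
  fn <- fold_of(length(negatives))

  fold_auc <- numeric(n_folds)
  rocs <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    fit <- train_classifier(positives[fp != k], negatives[fn != k],
                            config)
    held <- c(positives[fp == k], negatives[fn == k])
    lab <- c(rep(1L, sum(fp == k)), rep(0L, sum(fn == k)))
    sc <- score_sequences(fit, held)
    fold_auc[k] <- compute_auc(sc, lab)
    rocs[[k]] <- roc_points(sc, lab)
  }
  structure(
    list(fold_auc = fold_auc, mean_auc = mean(fold_auc), roc = rocs,
         folds = list(positives = fp, negatives = fn),
         n_folds = n_folds),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation\n", sep = "")
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$fold_auc),
                               collapse = ", "), "\n")
  cat("  mean AUC    :", sprintf("%.3f", x$mean_auc), "\n")
  invisible(x)
}
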