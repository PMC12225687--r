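# Compact transformer encoder for CDR3beta scoring, in plain R matrix code.
#
# Architecture: token embedding + fixed sinusoidal positional encoding,
# n_layers post-norm encoder blocks (multi-head self-attention with key
# padding mask -> add & layer-norm -> position-wise feed-forward (ReLU) ->
# add & layer-norm), masked mean pooling over real positions, and a linear
# head producing one pre-sigmoid score (log-odds) per sequence.
# Gradients are derived by hand and checked against finite differences in
# the test suite; training is Adam on binary cross-entropy.

#' Token vocabulary for CDR3beta sequences
#'
#' The 20 standard amino acids plus a padding token and begin/end markers.
#' Token/index mapping is bijective; padding is excluded from attention and
#' pooling via the mask.
#'
#' @param max_len maximum sequence length in residues (excluding the
#'   begin/end markers added by [encode_sequences()]).
#' @return A `token_vocab` list with `tokens`, `index` and `max_len`.
#' @export
token_vocab <- function(max_len = 24L) {
  tokens <- c("<pad>", "<bos>", "<eos>", aa_alphabet())
  structure(
    list(tokens = tokens,
         index = stats::setNames(seq_along(tokens), tokens),
         max_len = as.integer(max_len)),
    class = "token_vocab"
  )
}

#' Encode sequences to a padded token matrix with mask
#'
#' Sequences are wrapped in begin/end markers and right-padded to a common
#' width. The mask marks real tokens (markers included); encoding is
#' invertible for real positions via [decode_tokens()].
#'
#' @param seqs character vector over the standard amino-acid alphabet,
#'   each at most `vocab$max_len` residues.
#' @param vocab a [token_vocab()].
#' @return List with `tokens` (n x T integer matrix), `mask` (n x T
#'   logical) and `vocab`. For `n = 0` the matrices have zero rows.
#' @export
encode_sequences <- function(seqs, vocab = token_vocab()) {
  n <- length(seqs)
  T_ <- vocab$max_len + 2L
  if (n == 0L) {
    return(list(tokens = matrix(integer(), 0L, T_),
                mask = matrix(logical(), 0L, T_), vocab = vocab))
  }
  bad <- !is_standard_aa(seqs)
  if (any(bad)) {
    stop("sequence(s) contain non-standard amino acids: ",
         paste(utils::head(seqs[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  too_long <- nchar(seqs) > vocab$max_len
  if (any(too_long)) {
    stop("sequence(s) exceed max_len = ", vocab$max_len, ": ",
         paste(utils::head(seqs[too_long], 5L), collapse = ", "),
         call. = FALSE)
  }
  tokens <- matrix(vocab$index["<pad>"], n, T_)
  mask <- matrix(FALSE, n, T_)
  res <- split_residues(seqs)
  for (i in seq_len(n)) {
    ids <- c(vocab$index["<bos>"], vocab$index[res[[i]]],
             vocab$index["<eos>"])
    tokens[i, seq_along(ids)] <- ids
    mask[i, seq_along(ids)] <- TRUE
  }
  list(tokens = tokens, mask = mask, vocab = vocab)
}

#' Decode a token matrix back to sequences
#'
#' @param tokens n x T integer matrix from [encode_sequences()].
#' @param vocab the matching [token_vocab()].
#' @return Character vector of sequences (markers and padding removed).
#' @export
decode_tokens <- function(tokens, vocab = token_vocab()) {
  special <- vocab$index[c("<pad>", "<bos>", "<eos>")]
  apply(tokens, 1, function(row) {
    paste(vocab$tokens[row[!(row %in% special)]], collapse = "")
  })
}

# fixed sinusoidal positional encoding (T x d)
positional_encoding <- function(T_, d) {
  pos <- seq_len(T_) - 1L
  i <- seq_len(d) - 1L
  angle <- outer(pos, 10000^(-2 * (i %/% 2) / d))
  pe <- matrix(0, T_, d)
  even <- (i %% 2L) == 0L
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

# --- parameter initialization ------------------------------------------

init_params <- function(config, vocab) {
  d <- config$embedding_dim
  ff <- config$ff_dim
  V <- length(vocab$tokens)
  gl <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
           n_in, n_out)
  }
  layer <- function() {
    list(Wq = gl(d, d), bq = numeric(d),
         Wk = gl(d, d), bk = numeric(d),
         Wv = gl(d, d), bv = numeric(d),
         Wo = gl(d, d), bo = numeric(d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = gl(d, ff), b1 = numeric(ff),
         W2 = gl(ff, d), b2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  list(E = gl(V, d),
       layers = lapply(seq_len(config$n_layers), function(l) layer()),
       head_w = stats::rnorm(d, sd = 1 / sqrt(d)), head_b = 0)
}

# --- parameter-tree utilities ------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
  } else {
    f(a, b)
  }
}
tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

# --- layer norm --------------------------------------------------------

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv_sd = inv_sd)
}

layernorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx, dg = dg, db = db)
}

# --- forward pass ------------------------------------------------------

# tokens/mask: n x T; returns logits and (optionally) caches for backprop
transformer_forward <- function(params, tokens, mask, config,
                                dropout_p = 0, keep_cache = FALSE) {
  n <- nrow(tokens)
  T_ <- ncol(tokens)
  d <- config$embedding_dim
  H <- config$n_heads
  dk <- d %/% H
  pe <- positional_encoding(T_, d)

  drop_mask <- function(dim_r, dim_c) {
    if (dropout_p <= 0) return(NULL)
    matrix(stats::rbinom(dim_r * dim_c, 1L, 1 - dropout_p), dim_r,
           dim_c) / (1 - dropout_p)
  }

  # stacked rows: sequence i occupies rows (i-1)*T + 1:T
  X <- params$E[as.vector(t(tokens)), , drop = FALSE] +
    pe[rep(seq_len(T_), n), , drop = FALSE]
  emb_drop <- drop_mask(n * T_, d)
  if (!is.null(emb_drop)) X <- X * emb_drop

  caches <- list(tokens = tokens, mask = mask, emb_drop = emb_drop,
                 layers = vector("list", config$n_layers))
  head_cols <- lapply(seq_len(H), function(h) ((h - 1L) * dk + 1L):(h * dk))

  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    Xin <- X
    Q <- Xin %*% lp$Wq + rep(lp$bq, each = n * T_)
    K <- Xin %*% lp$Wk + rep(lp$bk, each = n * T_)
    V <- Xin %*% lp$Wv + rep(lp$bv, each = n * T_)
    ctx <- matrix(0, n * T_, d)
    att <- if (keep_cache) vector("list", n) else NULL
    for (i in seq_len(n)) {
      rows <- ((i - 1L) * T_ + 1L):(i * T_)
      ki <- mask[i, ]
      att_i <- if (keep_cache) vector("list", H) else NULL
      for (h in seq_len(H)) {
        cols <- head_cols[[h]]
        S <- (Q[rows, cols, drop = FALSE] %*%
                t(K[rows, cols, drop = FALSE])) / sqrt(dk)
        S[, !ki] <- -Inf
        S <- S - S[cbind(seq_len(T_), max.col(S, ties.method = "first"))]
        P <- exp(S)
        P <- P / rowSums(P)
        ctx[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
        if (keep_cache) att_i[[h]] <- P
      }
      if (keep_cache) att[[i]] <- att_i
    }
    O <- ctx %*% lp$Wo + rep(lp$bo, each = n * T_)
    att_drop <- drop_mask(n * T_, d)
    if (!is.null(att_drop)) O <- O * att_drop
    ln1 <- layernorm_forward(Xin + O, lp$ln1_g, lp$ln1_b)
    X1 <- ln1$y
    Hpre <- X1 %*% lp$W1 + rep(lp$b1, each = n * T_)
    Hact <- pmax(Hpre, 0)
    F_ <- Hact %*% lp$W2 + rep(lp$b2, each = n * T_)
    ff_drop <- drop_mask(n * T_, d)
    if (!is.null(ff_drop)) F_ <- F_ * ff_drop
    ln2 <- layernorm_forward(X1 + F_, lp$ln2_g, lp$ln2_b)
    X <- ln2$y
    if (keep_cache) {
      caches$layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V,
                                 ctx = ctx, att = att,
                                 att_drop = att_drop, ln1 = ln1, X1 = X1,
                                 Hact = Hact, ff_drop = ff_drop, ln2 = ln2)
    }
  }

  # masked mean pooling
  pooled <- matrix(0, n, d)
  n_real <- rowSums(mask)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * T_ + 1L):(i * T_)
    pooled[i, ] <- colSums(X[rows, , drop = FALSE][mask[i, ], ,
                                                   drop = FALSE]) /
      n_real[i]
  }
  logits <- as.vector(pooled %*% params$head_w) + params$head_b
  if (keep_cache) {
    caches$X_final <- X
    caches$pooled <- pooled
    caches$n_real <- n_real
  }
  list(logits = logits, cache = if (keep_cache) caches else NULL)
}

# --- backward pass -----------------------------------------------------

# dlogits: vector length n; returns gradient tree matching params
transformer_backward <- function(params, cache, dlogits, config) {
  tokens <- cache$tokens
  mask <- cache$mask
  n <- nrow(tokens)
  T_ <- ncol(tokens)
  d <- config$embedding_dim
  H <- config$n_heads
  dk <- d %/% H
  head_cols <- lapply(seq_len(H), function(h) ((h - 1L) * dk + 1L):(h * dk))

  grads <- tree_zero(params)
  grads$head_w <- as.vector(t(cache$pooled) %*% dlogits)
  grads$head_b <- sum(dlogits)

  # gradient into the final stream X
  dX <- matrix(0, n * T_, d)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * T_ + 1L):(i * T_)
    contrib <- (dlogits[i] / cache$n_real[i]) * params$head_w
    dX[rows[mask[i, ]], ] <- matrix(contrib, sum(mask[i, ]), d,
                                    byrow = TRUE)
  }

  for (l in rev(seq_len(config$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- grads$layers[[l]]

    ln2b <- layernorm_backward(dX, lc$ln2, lp$ln2_g)
    gl$ln2_g <- ln2b$dg; gl$ln2_b <- ln2b$db
    dsum2 <- ln2b$dx                       # grad of (X1 + F)
    dF <- dsum2
    if (!is.null(lc$ff_drop)) dF <- dF * lc$ff_drop
    gl$W2 <- t(lc$Hact) %*% dF
    gl$b2 <- colSums(dF)
    dHact <- dF %*% t(lp$W2)
    dHpre <- dHact * (lc$Hact > 0)
    gl$W1 <- t(lc$X1) %*% dHpre
    gl$b1 <- colSums(dHpre)
    dX1 <- dsum2 + dHpre %*% t(lp$W1)

    ln1b <- layernorm_backward(dX1, lc$ln1, lp$ln1_g)
    gl$ln1_g <- ln1b$dg; gl$ln1_b <- ln1b$db
    dsum1 <- ln1b$dx                       # grad of (Xin + O)
    dO <- dsum1
    if (!is.null(lc$att_drop)) dO <- dO * lc$att_drop
    gl$Wo <- t(lc$ctx) %*% dO
    gl$bo <- colSums(dO)
    dctx <- dO %*% t(lp$Wo)

    dQ <- matrix(0, n * T_, d)
    dK <- matrix(0, n * T_, d)
    dV <- matrix(0, n * T_, d)
    for (i in seq_len(n)) {
      rows <- ((i - 1L) * T_ + 1L):(i * T_)
      for (h in seq_len(H)) {
        cols <- head_cols[[h]]
        P <- lc$att[[i]][[h]]
        dctx_h <- dctx[rows, cols, drop = FALSE]
        dP <- dctx_h %*% t(lc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- dV[rows, cols] + t(P) %*% dctx_h
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(dk)
        dQ[rows, cols] <- dQ[rows, cols] +
          dS %*% lc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- dK[rows, cols] +
          t(dS) %*% lc$Q[rows, cols, drop = FALSE]
      }
    }
    gl$Wq <- t(lc$Xin) %*% dQ; gl$bq <- colSums(dQ)
    gl$Wk <- t(lc$Xin) %*% dK; gl$bk <- colSums(dK)
    gl$Wv <- t(lc$Xin) %*% dV; gl$bv <- colSums(dV)
    dXin <- dsum1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)

    grads$layers[[l]] <- gl
    dX <- dXin
  }

  if (!is.null(cache$emb_drop)) dX <- dX * cache$emb_drop
  tok_vec <- as.vector(t(tokens))
  for (v in unique(tok_vec)) {
    sel <- tok_vec == v
    grads$E[v, ] <- colSums(dX[sel, , drop = FALSE])
  }
  grads
}

# --- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# numerically stable binary cross-entropy with logits; returns mean loss
# and per-sample gradient
bce_with_logits <- function(logits, y) {
  loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  dlogits <- (stats::plogis(logits) - y) / length(y)
  list(loss = loss, dlogits = dlogits)
}
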