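## Bidirectional LSTM classifiers, implemented directly in vectorized R.
##
## Two architectures:
##   * basic   -- Bi-LSTM (final state of each direction) -> dense(ReLU)
##                -> dense(2, softmax);
##   * selfatt -- Bi-LSTM (per-position outputs) -> additive self-attention
##                over position pairs -> attention pooling (softmax-weighted
##                sum over positions) -> dense(ReLU) -> dense(2, softmax).
##
## The output pair is (P(non-ACP), P(ACP)). Pad rows are not masked: padding
## is all-zero by construction of the encoders, and the network is trained on
## fixed-width inputs (a masking switch exists but defaults off).

#' Model configuration
#'
#' Bundles the feature scheme, architecture and training hyper-parameters.
#' Grid-search optima reported for this model family put `n_units` at 64/128
#' with a 50-neuron first dense layer; defaults follow the smaller optimum.
#'
#' @param scheme Feature scheme name (see [feature_scheme()]); `"embedding"`
#'   selects a trainable 20 x 36 residue lookup in place of fixed features.
#' @param architecture `"basic"` or `"selfatt"`.
#' @param n_units LSTM units per direction (the per-position Bi-LSTM output
#'   is `2 * n_units` wide).
#' @param dense_units Neurons in the first fully connected layer.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param attention_width Hidden width of the self-attention score path.
#' @param lmax Padded sequence length.
#' @param mask_padding If `TRUE`, positions beyond each peptide's true length
#'   are excluded from attention softmaxes and the LSTM state is frozen past
#'   the end of the sequence. Off by default.
#' @return An object of class `acp_config` (a validated list).
#' @export
#' @examples
#' model_config(n_units = 32, epochs = 15)
model_config <- function(scheme = "mix", architecture = c("basic", "selfatt"),
                         n_units = 64L, dense_units = 50L, epochs = 45L,
                         batch_size = 32L, learning_rate = 1e-3, seed = 1L,
                         attention_width = 32L, lmax = LMAX_DEFAULT,
                         mask_padding = FALSE) {
  architecture <- match.arg(architecture)
  scheme <- feature_scheme(if (inherits(scheme, "acp_scheme")) scheme$name else scheme)
  for (nm in c("n_units", "dense_units", "epochs", "batch_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1L) {
      abort_validation(paste0(nm, " must be a positive integer"))
    }
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    abort_validation("learning_rate must be positive")
  }
  structure(list(
    scheme = scheme, architecture = architecture,
    n_units = as.integer(n_units), dense_units = as.integer(dense_units),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed),
    attention_width = as.integer(attention_width), lmax = as.integer(lmax),
    mask_padding = isTRUE(mask_padding)
  ), class = "acp_config")
}

#' @export
print.acp_config <- function(x, ...) {
  cat(sprintf(
    "<acp_config> %s / %s: n_units=%d dense=%d epochs=%d batch=%d lr=%g seed=%d\n",
    x$architecture, x$scheme$name, x$n_units, x$dense_units, x$epochs,
    x$batch_size, x$learning_rate, x$seed
  ))
  invisible(x)
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_lstm <- function(d, n) {
  b <- numeric(4L * n)
  b[(n + 1L):(2L * n)] <- 1  # forget-gate bias starts open
  list(Wx = glorot(d, 4L * n), Wh = glorot(n, 4L * n), b = b)
}

#' Build an (untrained) model
#'
#' Initializes all parameters from the seeded generator; two builds with the
#' same config are identical.
#'
#' @param config An [model_config()] object.
#' @return An object of class `acp_model` with elements `config`, `params`,
#'   `standardization` (the z-score snapshot used by quantitative channels),
#'   `channel_names`, `trained`, `training_log` and `version`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "acp_config"))
  n <- config$n_units
  d <- config$scheme$d
  params <- with_seed(config$seed, {
    p <- list(
      lstm_f = init_lstm(d, n),
      lstm_b = init_lstm(d, n),
      dense = list(
        W1 = glorot(2L * n, config$dense_units), b1 = numeric(config$dense_units),
        W2 = glorot(config$dense_units, 2L), b2 = numeric(2L)
      )
    )
    if (config$architecture == "selfatt") {
      da <- config$attention_width
      p$sa <- list(
        Wt = glorot(2L * n, da), Wx = glorot(2L * n, da), bt = numeric(da),
        wa = as.numeric(glorot(da, 1L)), ba = 0
      )
      p$att <- list(W = as.numeric(glorot(2L * n, 1L)), b = numeric(config$lmax))
    }
    if (config$scheme$name == "embedding") {
      p$emb <- glorot(20L, 36L)
    }
    p
  })
  structure(list(
    config = config,
    params = params,
    standardization = if (config$scheme$name %in% c("quanc", "mix")) {
      std_quant_matrix()
    } else {
      NULL
    },
    channel_names = config$scheme$channel_names,
    trained = FALSE,
    training_log = tibble::tibble(epoch = integer(), loss = numeric()),
    version = as.character(utils::packageVersion("acplearn"))
  ), class = "acp_model")
}

#' @export
print.acp_model <- function(x, ...) {
  cat(sprintf(
    "<acp_model> %s/%s (%strained)\n", x$config$architecture,
    x$config$scheme$name, if (x$trained) "" else "un"
  ))
  invisible(x)
}

## ---- LSTM ------------------------------------------------------------

## One direction over a B x L x d input. Returns per-position hidden states
## H (B x L x n) and, when cache = TRUE, the gate activations needed by BPTT.
## `lengths` (with masking on) freezes the state once t exceeds a sequence's
## true length, so the final state equals the state at the last real residue.
lstm_forward <- function(X, p, reverse = FALSE, cache = TRUE, lengths = NULL) {
  dm <- dim(X)
  B <- dm[1L]; L <- dm[2L]
  n <- nrow(p$Wh)
  ord <- if (reverse) L:1 else 1:L
  H <- array(0, c(B, L, n))
  ch <- if (cache) {
    list(I = array(0, c(B, L, n)), Fg = array(0, c(B, L, n)),
         O = array(0, c(B, L, n)), G = array(0, c(B, L, n)),
         C = array(0, c(B, L, n)), Tc = array(0, c(B, L, n)), ord = ord)
  } else {
    NULL
  }
  h <- matrix(0, B, n)
  c_ <- matrix(0, B, n)
  for (t in ord) {
    z <- slice_t(X, t) %*% p$Wx + h %*% p$Wh
    z <- z + rep(p$b, each = B)
    I <- sigmoid(z[, 1:n, drop = FALSE])
    Fg <- sigmoid(z[, (n + 1L):(2L * n), drop = FALSE])
    O <- sigmoid(z[, (2L * n + 1L):(3L * n), drop = FALSE])
    G <- tanh(z[, (3L * n + 1L):(4L * n), drop = FALSE])
    c_new <- Fg * c_ + I * G
    tc <- tanh(c_new)
    h_new <- O * tc
    if (!is.null(lengths)) {
      active <- as.numeric(lengths >= t)
      c_new <- active * c_new + (1 - active) * c_
      h_new <- active * h_new + (1 - active) * h
    }
    c_ <- c_new
    h <- h_new
    H[, t, ] <- h
    if (cache) {
      ch$I[, t, ] <- I; ch$Fg[, t, ] <- Fg; ch$O[, t, ] <- O
      ch$G[, t, ] <- G; ch$C[, t, ] <- c_; ch$Tc[, t, ] <- tc
    }
  }
  list(H = H, cache = ch)
}

## ---- attention layers ------------------------------------------------

## Batched attention pooling: H (B x L x D), W (D), b (L).
## e[b, j] = H[b, j, ] . W + b[j]; alpha = softmax rows; out = sum_j alpha * H_j.
attention_pool_batch <- function(H, p, mask = NULL) {
  dm <- dim(H)
  B <- dm[1L]; L <- dm[2L]; D <- dm[3L]
  Hmat <- matrix(H, B * L, D)          # row index b + (j-1)B
  E <- matrix(Hmat %*% p$W, B, L) + rep(p$b, each = B)
  if (!is.null(mask)) E[!mask] <- -Inf
  alpha <- softmax_rows(E)
  out <- rowsum(Hmat * as.vector(alpha), rep(seq_len(B), times = L))
  list(out = out, alpha = alpha, Hmat = Hmat)
}

#' Attention pooling over sequence positions
#'
#' Scores every position of a `Lmax x 2n` representation with a trainable
#' vector `W` and per-position bias `b`, softmax-normalizes the scores, and
#' returns the weighted sum of the rows.
#'
#' @param h Numeric `Lmax x 2n` matrix (per-position representation of one
#'   sequence).
#' @param W Numeric weight vector of length `2n`.
#' @param b Numeric bias vector of length `Lmax`.
#' @return A list with `pooled` (length-`2n` vector) and `alpha` (length-
#'   `Lmax` softmax weights, summing to 1).
#' @export
#' @examples
#' h <- matrix(rnorm(10), 5, 2)
#' attention_pool(h, W = c(0, 0), b = numeric(5))$alpha # uniform 1/5
attention_pool <- function(h, W, b) {
  if (!is.matrix(h) || length(W) != ncol(h) || length(b) != nrow(h)) {
    abort_validation("attention_pool(): need h (L x 2n), W of length 2n, b of length L")
  }
  H <- array(h, c(1L, nrow(h), ncol(h)))
  res <- attention_pool_batch(H, list(W = W, b = b))
  list(pooled = as.numeric(res$out[1L, ]), alpha = as.numeric(res$alpha[1L, ]))
}

## Additive self-attention for one sequence. X (L x D); params Wt, Wx
## (D x da), bt (da), wa (da), ba (scalar). Returns the recombined rows
## l = A X plus the caches used by the backward pass.
sa_forward_one <- function(X, p, cache = TRUE, mask = NULL) {
  L <- nrow(X)
  U <- X %*% p$Wt
  V <- X %*% p$Wx
  ## pair rows ordered t fastest: row r = t + (t'-1) L
  Tt <- tanh(U[rep(seq_len(L), times = L), , drop = FALSE] +
    V[rep(seq_len(L), each = L), , drop = FALSE] +
    rep(p$bt, each = L * L))
  E <- sigmoid(matrix(Tt %*% p$wa + p$ba, L, L))  # E[t, t']
  Elog <- E
  if (!is.null(mask)) Elog[, !mask] <- -Inf
  A <- softmax_rows(Elog)
  out <- A %*% X
  if (cache) list(out = out, A = A, E = E, Tt = Tt, U = U, V = V) else list(out = out, A = A)
}

#' Additive self-attention over residue positions
#'
#' Scores every ordered pair of positions (t, t') of a `Lmax x 2n`
#' representation with a one-hidden-layer additive score
#' `e[t, t'] = sigmoid(wa . tanh(x_t Wt + x_t' Wx + bt) + ba)`, softmax-
#' normalizes each row over t', and recombines the input rows:
#' `l_t = sum_t' a[t, t'] x_t'`.
#'
#' @param x Numeric `Lmax x 2n` matrix.
#' @param params List with `Wt`, `Wx` (`2n x da`), `bt` (`da`), `wa` (`da`),
#'   `ba` (scalar).
#' @return A list with `out` (`Lmax x 2n` recombined representation) and
#'   `attention` (`Lmax x Lmax` matrix whose rows sum to 1).
#' @export
self_attention <- function(x, params) {
  if (!is.matrix(x) || nrow(params$Wt) != ncol(x) || nrow(params$Wx) != ncol(x)) {
    abort_validation("self_attention(): x must be L x 2n and Wt/Wx 2n x da")
  }
  res <- sa_forward_one(x, params, cache = FALSE)
  list(out = res$out, attention = res$A)
}

## ---- full forward pass -----------------------------------------------

## X: encoded array (n x L x d) or, for the embedding scheme, an integer
## index matrix (n x L). Returns probabilities, penultimate activations and
## (cache = TRUE) everything the backward pass needs.
forward_pass <- function(params, config, X, cache = FALSE, lengths = NULL) {
  n <- config$n_units
  emb_idx <- NULL
  if (config$scheme$name == "embedding") {
    emb_idx <- X
    B <- nrow(emb_idx); L <- ncol(emb_idx)
    Xe <- array(0, c(B, L, ncol(params$emb)))
    lookup <- rbind(0, params$emb)  # row 1 = padding
    Xe <- array(lookup[as.vector(emb_idx) + 1L, ], c(B, L, ncol(params$emb)))
    X <- Xe
  }
  dm <- dim(X)
  B <- dm[1L]; L <- dm[2L]
  lens <- if (config$mask_padding) lengths else NULL
  fwd_f <- lstm_forward(X, params$lstm_f, reverse = FALSE, cache = cache, lengths = lens)
  fwd_b <- lstm_forward(X, params$lstm_b, reverse = TRUE, cache = cache, lengths = lens)
  sa_caches <- NULL
  ap_cache <- NULL
  if (config$architecture == "basic") {
    ## With masking on, the forward state is frozen past each true length, so
    ## slice L is the state at the last real residue in either case.
    feat <- cbind(matrix(fwd_f$H[, L, ], B, n), matrix(fwd_b$H[, 1L, ], B, n))
  } else {
    H <- array(0, c(B, L, 2L * n))
    H[, , 1:n] <- fwd_f$H
    H[, , (n + 1L):(2L * n)] <- fwd_b$H
    Hsa <- array(0, c(B, L, 2L * n))
    sa_caches <- vector("list", B)
    for (i in seq_len(B)) {
      mask_i <- if (is.null(lens)) NULL else seq_len(L) <= lens[i]
      r <- sa_forward_one(matrix(H[i, , ], L, 2L * n), params$sa,
        cache = cache, mask = mask_i
      )
      Hsa[i, , ] <- r$out
      if (cache) sa_caches[[i]] <- r
    }
    mask_mat <- if (is.null(lens)) {
      NULL
    } else {
      outer(lens, seq_len(L), ">=")
    }
    ap <- attention_pool_batch(Hsa, params$att, mask = mask_mat)
    ap_cache <- ap
    feat <- ap$out
  }
  A1pre <- feat %*% params$dense$W1 + rep(params$dense$b1, each = B)
  A1 <- relu(A1pre)
  logits <- A1 %*% params$dense$W2 + rep(params$dense$b2, each = B)
  probs <- softmax_rows(logits)
  colnames(probs) <- c("p_non_acp", "p_acp")
  out <- list(probs = probs, penultimate = A1)
  if (cache) {
    out$cache <- list(
      X = X, emb_idx = emb_idx, fwd_f = fwd_f, fwd_b = fwd_b,
      sa_caches = sa_caches, ap = ap_cache, feat = feat,
      A1pre = A1pre, A1 = A1, lengths = lens
    )
  }
  out
}
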