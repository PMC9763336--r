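## Reverse-mode gradients for the network in network.R. Everything here is
## checked against finite differences in the test suite.

## Backprop through one LSTM direction. dH: B x L x n gradient w.r.t. every
## per-position hidden state. Returns parameter gradients, and dX when
## need_dX (used by the trainable-embedding scheme).
lstm_backward <- function(X, p, fwd, dH, need_dX = FALSE, lengths = NULL) {
  dm <- dim(X)
  B <- dm[1L]; L <- dm[2L]; d <- dm[3L]
  n <- nrow(p$Wh)
  ch <- fwd$cache
  ord <- ch$ord
  dWx <- matrix(0, d, 4L * n)
  dWh <- matrix(0, n, 4L * n)
  db <- numeric(4L * n)
  dX <- if (need_dX) array(0, c(B, L, d)) else NULL
  dh_next <- matrix(0, B, n)
  dc_next <- matrix(0, B, n)
  for (k in L:1) {
    t <- ord[k]
    active <- if (is.null(lengths)) 1 else as.numeric(lengths >= t)
    h_prev <- if (k == 1L) matrix(0, B, n) else matrix(fwd$H[, ord[k - 1L], ], B, n)
    c_prev <- if (k == 1L) matrix(0, B, n) else matrix(ch$C[, ord[k - 1L], ], B, n)
    I <- matrix(ch$I[, t, ], B, n); Fg <- matrix(ch$Fg[, t, ], B, n)
    O <- matrix(ch$O[, t, ], B, n); G <- matrix(ch$G[, t, ], B, n)
    tc <- matrix(ch$Tc[, t, ], B, n)
    dh <- matrix(dH[, t, ], B, n) + dh_next
    dh_new <- dh * active
    dc_in <- dc_next
    dc_new <- dc_in * active + dh_new * O * (1 - tc^2)
    do_ <- dh_new * tc
    di <- dc_new * G
    df <- dc_new * c_prev
    dg <- dc_new * I
    dz <- cbind(
      di * I * (1 - I), df * Fg * (1 - Fg), do_ * O * (1 - O), dg * (1 - G^2)
    )
    x_t <- slice_t(X, t)
    dWx <- dWx + crossprod(x_t, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(p$Wh) + dh * (1 - active)
    dc_next <- dc_new * Fg + dc_in * (1 - active)
    if (need_dX) dX[, t, ] <- dz %*% t(p$Wx)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

## Backprop through additive self-attention for one sequence.
## dL_out: L x D gradient w.r.t. the recombined rows.
sa_backward_one <- function(X, p, cache, dL_out) {
  L <- nrow(X)
  A <- cache$A
  E <- cache$E
  Tt <- cache$Tt
  dA <- dL_out %*% t(X)                    # L x L
  dX <- t(A) %*% dL_out
  dE <- A * (dA - rowSums(A * dA))         # softmax rows
  ds <- dE * E * (1 - E)                   # sigmoid
  ds_vec <- as.vector(ds)                  # index t + (t'-1)L, matches Tt rows
  dwa <- as.numeric(crossprod(Tt, ds_vec))
  dba <- sum(ds_vec)
  dM <- (ds_vec %o% p$wa) * (1 - Tt^2)     # (L^2) x da
  dU <- rowsum(dM, rep(seq_len(L), times = L))
  dV <- rowsum(dM, rep(seq_len(L), each = L))
  dbt <- colSums(dM)
  list(
    dX = dX + dU %*% t(p$Wt) + dV %*% t(p$Wx),
    Wt = crossprod(X, dU), Wx = crossprod(X, dV), bt = dbt,
    wa = dwa, ba = dba
  )
}

## Backprop through batched attention pooling. dout: B x D.
attention_pool_backward <- function(ap, p, dout, B, L, D) {
  alpha_vec <- as.vector(ap$alpha)         # index b + (j-1)B, matches Hmat
  dout_rep <- dout[rep(seq_len(B), times = L), , drop = FALSE]
  dalpha <- matrix(rowSums(ap$Hmat * dout_rep), B, L)
  de <- ap$alpha * (dalpha - rowSums(ap$alpha * dalpha))
  dW <- as.numeric(crossprod(ap$Hmat, as.vector(de)))
  db <- colSums(de)
  dHmat <- as.vector(de) %o% p$W + alpha_vec * dout_rep
  list(dH = array(dHmat, c(B, L, D)), W = dW, b = db)
}

## Full backward pass. fw: forward_pass(..., cache = TRUE) result;
## dlogits: B x 2 gradient of the loss w.r.t. the output logits.
backward_pass <- function(params, config, fw, dlogits) {
  ch <- fw$cache
  B <- nrow(dlogits)
  n <- config$n_units
  L <- config$lmax
  grads <- list()
  ## dense head
  dW2 <- crossprod(ch$A1, dlogits)
  db2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(params$dense$W2)
  dA1pre <- dA1 * (ch$A1pre > 0)
  dW1 <- crossprod(ch$feat, dA1pre)
  db1 <- colSums(dA1pre)
  dfeat <- dA1pre %*% t(params$dense$W1)
  grads$dense <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  ## route dfeat back to the per-position hidden states
  dHf <- array(0, c(B, L, n))
  dHb <- array(0, c(B, L, n))
  if (config$architecture == "basic") {
    dHf[, L, ] <- dfeat[, 1:n, drop = FALSE]
    dHb[, 1L, ] <- dfeat[, (n + 1L):(2L * n), drop = FALSE]
  } else {
    apb <- attention_pool_backward(ch$ap, params$att, dfeat, B, L, 2L * n)
    grads$att <- list(W = apb$W, b = apb$b)
    dH <- array(0, c(B, L, 2L * n))   # gradient w.r.t. Bi-LSTM output rows
    gsa <- list(
      Wt = matrix(0, 2L * n, config$attention_width),
      Wx = matrix(0, 2L * n, config$attention_width),
      bt = numeric(config$attention_width),
      wa = numeric(config$attention_width), ba = 0
    )
    for (i in seq_len(B)) {
      Xi <- matrix(0, L, 2L * n)
      Xi[, 1:n] <- ch$fwd_f$H[i, , ]
      Xi[, (n + 1L):(2L * n)] <- ch$fwd_b$H[i, , ]
      bi <- sa_backward_one(Xi, params$sa, ch$sa_caches[[i]],
                            matrix(apb$dH[i, , ], L, 2L * n))
      dH[i, , ] <- bi$dX
      gsa$Wt <- gsa$Wt + bi$Wt; gsa$Wx <- gsa$Wx + bi$Wx
      gsa$bt <- gsa$bt + bi$bt; gsa$wa <- gsa$wa + bi$wa; gsa$ba <- gsa$ba + bi$ba
    }
    grads$sa <- gsa
    dHf <- dH[, , 1:n, drop = FALSE]
    dHb <- dH[, , (n + 1L):(2L * n), drop = FALSE]
  }
  need_dX <- config$scheme$name == "embedding"
  bf <- lstm_backward(ch$X, params$lstm_f, ch$fwd_f, dHf,
                      need_dX = need_dX, lengths = ch$lengths)
  bb <- lstm_backward(ch$X, params$lstm_b, ch$fwd_b, dHb,
                      need_dX = need_dX, lengths = ch$lengths)
  grads$lstm_f <- bf[c("Wx", "Wh", "b")]
  grads$lstm_b <- bb[c("Wx", "Wh", "b")]
  if (need_dX) {
    dX <- bf$dX + bb$dX
    demb <- matrix(0, 20L, ncol(params$emb))
    idx_vec <- as.vector(ch$emb_idx)
    dX_mat <- matrix(dX, length(idx_vec), ncol(params$emb))
    keep <- idx_vec > 0L
    demb_acc <- rowsum(dX_mat[keep, , drop = FALSE], idx_vec[keep])
    demb[as.integer(rownames(demb_acc)), ] <- demb_acc
    grads$emb <- demb
  }
  grads
}

## ---- parameter-tree utilities and Adam --------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

## Combine two parameter trees leaf-wise. Matched by name (the gradient tree
## is not built in the same order as the parameter tree).
tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    keys <- names(x) %||% seq_along(x)
    for (i in seq_along(x)) {
      out[[i]] <- tree_map2(x[[i]], y[[keys[i]]], f)
    }
    out
  } else {
    f(x, y)
  }
}

adam_init <- function(params) {
  list(
    m = tree_map(params, function(p) p * 0),
    v = tree_map(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

## Cross-entropy of softmax probabilities against one-hot labels Y (B x 2).
cross_entropy <- function(probs, Y) {
  -mean(log(rowSums(probs * Y) + 1e-12))
}
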