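## Internal numeric helpers shared by the network and explanation code.

sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise softmax of a matrix, numerically shifted by the row maximum.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## Slice timestep t out of a B x L x d array as a B x d matrix (dims kept
## even when B == 1).
slice_t <- function(X, t) {
  d <- dim(X)
  matrix(X[, t, ], nrow = d[1L], ncol = d[3L])
}

## Population standard deviation (divide by N, not N - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

## Run `expr` under a private RNG state seeded with `seed`; the caller's RNG
## stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Structured error/warning wrappers so the CLI can map condition classes to
## exit codes.
abort_io <- function(message, ...) {
  abort(message, class = "acplearn_io_error", ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = "acplearn_validation_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
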