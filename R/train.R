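## Model training and prediction.

encode_for_model <- function(config, peptides) {
  encode_dataset(peptides, scheme = config$scheme, lmax = config$lmax)
}

subset_encoded <- function(X, rows) {
  if (is.matrix(X)) {
    out <- X[rows, , drop = FALSE]
  } else {
    out <- X[rows, , , drop = FALSE]
  }
  for (a in c("ids", "lengths")) {
    attr(out, a) <- attr(X, a)[rows]
  }
  for (a in c("scheme", "channel_names")) attr(out, a) <- attr(X, a)
  out
}

#' Train a classifier
#'
#' Trains the configured network on a labeled peptide dataset with Adam and
#' categorical cross-entropy on the softmax output pair, for exactly
#' `config$epochs` epochs. Deterministic given `config$seed`: the same config
#' and data always give the same model.
#'
#' @param config An [model_config()] object.
#' @param peptides A fully labeled peptide tibble.
#' @return A trained `acp_model` with a per-epoch `training_log`.
#' @export
#' @examples
#' \donttest{
#' bench <- make_benchmark(n_pos = 20, n_neg = 20, seed = 1)
#' cfg <- model_config(n_units = 8, dense_units = 8, epochs = 3, seed = 1)
#' fit <- train_model(cfg, bench)
#' }
train_model <- function(config, peptides) {
  stopifnot(inherits(config, "acp_config"))
  peptides <- validate_peptides(peptides, lmax = config$lmax)
  require_labels(peptides, "train_model()")
  if (length(unique(peptides$label)) < 2L) {
    abort_validation("training data must contain both classes")
  }
  X <- encode_for_model(config, peptides)
  Y <- cbind(1 - peptides$label, peptides$label)  # (non-ACP, ACP)
  model <- build_model(config)
  params <- model$params
  n_obs <- nrow(peptides)
  losses <- numeric(config$epochs)
  state <- adam_init(params)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_obs)
      batch_starts <- seq(1L, n_obs, by = config$batch_size)
      epoch_loss <- 0
      for (s in batch_starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n_obs)]
        Xb <- subset_encoded(X, rows)
        Yb <- Y[rows, , drop = FALSE]
        fw <- forward_pass(params, config, Xb,
          cache = TRUE, lengths = attr(Xb, "lengths")
        )
        epoch_loss <- epoch_loss + cross_entropy(fw$probs, Yb) * length(rows)
        dlogits <- (fw$probs - Yb) / length(rows)
        grads <- backward_pass(params, config, fw, dlogits)
        st <- adam_step(params, grads, state, lr = config$learning_rate)
        params <- st$params
        state <- st$state
      }
      losses[epoch] <- epoch_loss / n_obs
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$training_log <- tibble::tibble(epoch = seq_len(config$epochs), loss = losses)
  model
}

## Forward a dataset through a model in memory-bounded chunks.
model_forward <- function(model, peptides, chunk_size = 256L, cache = FALSE) {
  X <- encode_for_model(model$config, peptides)
  n <- nrow(peptides)
  probs <- matrix(0, n, 2L)
  penult <- matrix(0, n, model$config$dense_units)
  for (s in seq(1L, n, by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, n)
    Xb <- subset_encoded(X, rows)
    fw <- forward_pass(model$params, model$config, Xb,
      cache = FALSE, lengths = attr(Xb, "lengths")
    )
    probs[rows, ] <- fw$probs
    penult[rows, ] <- fw$penultimate
  }
  colnames(probs) <- c("p_non_acp", "p_acp")
  list(probs = probs, penultimate = penult)
}

#' Predict class probabilities for peptides
#'
#' @param object A trained `acp_model`.
#' @param new_data A peptide tibble.
#' @param threshold Decision threshold on `P(ACP)`; probabilities `>=`
#'   threshold are called ACP (ties count as positive).
#' @param ... Unused.
#' @return A tibble with columns `id`, `p_non_acp`, `p_acp`, `pred` (0/1).
#'   Each probability row is nonnegative and sums to 1.
#' @export
predict.acp_model <- function(object, new_data, threshold = 0.5, ...) {
  new_data <- validate_peptides(new_data, lmax = object$config$lmax)
  fw <- model_forward(object, new_data)
  tibble::tibble(
    id = new_data$id,
    p_non_acp = unname(fw$probs[, 1L]),
    p_acp = unname(fw$probs[, 2L]),
    pred = as.integer(fw$probs[, 2L] >= threshold)
  )
}

#' Penultimate-layer features
#'
#' Activations of the first fully connected layer (the layer before the
#' softmax output), one `dense_units`-vector per peptide. These are the
#' learned features used for PCA visualization of class separation.
#'
#' @param model A trained `acp_model`.
#' @param peptides A peptide tibble.
#' @return Numeric matrix `n x dense_units`, rownames = peptide ids.
#' @export
penultimate_features <- function(model, peptides) {
  peptides <- validate_peptides(peptides, lmax = model$config$lmax)
  fw <- model_forward(model, peptides)
  rownames(fw$penultimate) <- peptides$id
  fw$penultimate
}

#' Save / load a trained model
#'
#' The archive is a single RDS file containing the configuration, all trained
#' weights, the standardization snapshot, channel names and the package
#' version. Predictions from a reloaded model are bit-identical to the
#' in-memory model.
#'
#' @param model An `acp_model`.
#' @param path File path for the model archive.
#' @return `path` invisibly; `read_model()` returns the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort_io(paste0("model file not found: ", path))
  model <- readRDS(path)
  if (!inherits(model, "acp_model")) {
    abort_validation(paste0(path, " is not an acplearn model archive"))
  }
  model
}
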