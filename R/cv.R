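## Stratified K-fold cross-validation and MCC-driven grid search.

#' Stratified K-fold cross-validation
#'
#' Trains K models on complementary fold unions and evaluates each on its
#' held-out fold; per-fold metrics are averaged arithmetically (AUC included,
#' averaged per fold rather than pooled). Fold models are retrained from
#' scratch with fold-specific seeds (`config$seed + fold`) so the whole run
#' is reproducible.
#'
#' @param config An [model_config()] object.
#' @param peptides A fully labeled peptide tibble.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment (default `config$seed`).
#' @return An object of class `acp_cv`: list with `folds` (K-row metrics
#'   tibble), `mean` (one-row tibble), `config`, `split`.
#' @export
#' @examples
#' \donttest{
#' bench <- make_benchmark(n_pos = 20, n_neg = 20, seed = 1)
#' cfg <- model_config(n_units = 8, dense_units = 8, epochs = 3, seed = 1)
#' cv <- cross_validate(cfg, bench, k = 2)
#' glance(cv)
#' }
cross_validate <- function(config, peptides, k = 5L, seed = config$seed) {
  stopifnot(inherits(config, "acp_config"))
  peptides <- validate_peptides(peptides, lmax = config$lmax)
  require_labels(peptides, "cross_validate()")
  split <- stratified_kfold(peptides, k = k, seed = seed)
  fold_of <- split$fold[match(peptides$id, split$id)]
  fold_rows <- lapply(0:(k - 1L), function(f) {
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    fit <- train_model(fold_cfg, peptides[fold_of != f, ])
    held <- peptides[fold_of == f, ]
    preds <- predict(fit, held)
    dplyr::bind_cols(
      tibble::tibble(fold = f),
      evaluate_predictions(preds$p_acp, held$label)
    )
  })
  folds <- dplyr::bind_rows(fold_rows)
  mean_rec <- dplyr::summarise(
    folds,
    dplyr::across(c("acc", "sen", "spc", "mcc", "auc"), mean)
  )
  structure(
    list(folds = folds, mean = mean_rec, config = config, split = split),
    class = "acp_cv"
  )
}

#' @export
print.acp_cv <- function(x, ...) {
  cat(sprintf(
    "<acp_cv> %d folds | mean ACC %.2f%% Sen %.2f%% Spc %.2f%% MCC %.3f AUC %.3f\n",
    nrow(x$folds), x$mean$acc, x$mean$sen, x$mean$spc, x$mean$mcc, x$mean$auc
  ))
  invisible(x)
}

#' Hyper-parameter grid search by cross-validated MCC
#'
#' Cross-validates every configuration and selects the one with the highest
#' mean CV MCC; ties are broken by higher mean accuracy, then by fewer epochs
#' (the smaller model is preferred), then by grid order.
#'
#' @param grid A list of [model_config()] objects, or a data frame whose
#'   columns override [model_config()] arguments (one row per candidate).
#' @param peptides A fully labeled peptide tibble.
#' @param k Folds per candidate.
#' @param seed Fold-assignment seed shared by all candidates.
#' @param base_config Config the data-frame rows are merged into.
#' @return An object of class `acp_grid`: list with `results` (one row per
#'   candidate with its mean CV metrics), `cv` (list of `acp_cv`), `best`
#'   (the winning config) and `best_index`.
#' @export
grid_search <- function(grid, peptides, k = 5L, seed = 1L,
                        base_config = model_config()) {
  if (is.data.frame(grid)) {
    grid <- lapply(seq_len(nrow(grid)), function(i) {
      args <- as.list(grid[i, , drop = FALSE])
      do.call(model_config, modifyList(config_to_args(base_config), args))
    })
  }
  if (length(grid) == 0L) abort_validation("empty grid")
  stopifnot(all(vapply(grid, inherits, logical(1L), "acp_config")))
  cvs <- lapply(grid, cross_validate, peptides = peptides, k = k, seed = seed)
  results <- dplyr::bind_rows(lapply(seq_along(grid), function(i) {
    cfg <- grid[[i]]
    dplyr::bind_cols(
      tibble::tibble(
        candidate = i, scheme = cfg$scheme$name,
        architecture = cfg$architecture, n_units = cfg$n_units,
        dense_units = cfg$dense_units, epochs = cfg$epochs
      ),
      cvs[[i]]$mean
    )
  }))
  best_index <- order(-results$mcc, -results$acc, results$epochs,
                      results$candidate)[1L]
  structure(
    list(results = results, cv = cvs, best = grid[[best_index]],
         best_index = best_index),
    class = "acp_grid"
  )
}

#' @export
print.acp_grid <- function(x, ...) {
  cat(sprintf("<acp_grid> %d candidates, best:\n", nrow(x$results)))
  print(x$best)
  invisible(x)
}

## Recover the argument list that rebuilds a config (used to merge grid rows).
config_to_args <- function(config) {
  list(
    scheme = config$scheme$name, architecture = config$architecture,
    n_units = config$n_units, dense_units = config$dense_units,
    epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate, seed = config$seed,
    attention_width = config$attention_width, lmax = config$lmax,
    mask_padding = config$mask_padding
  )
}
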