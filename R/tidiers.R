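## broom-style tidiers for the package's result objects.

#' Tidy a cross-validation result
#'
#' @param x An `acp_cv` object.
#' @param ... Unused.
#' @return One row per fold with `fold`, `acc`, `sen`, `spc`, `mcc`, `auc`,
#'   confusion counts and `n`.
#' @method tidy acp_cv
#' @export
tidy.acp_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.acp_cv
#' @return One-row tibble with the fold-averaged `acc`, `sen`, `spc`, `mcc`,
#'   `auc` plus `k`.
#' @method glance acp_cv
#' @export
glance.acp_cv <- function(x, ...) {
  dplyr::bind_cols(x$mean, tibble::tibble(k = nrow(x$folds)))
}

#' Tidy a grid-search result
#'
#' @param x An `acp_grid` object.
#' @param ... Unused.
#' @return One row per candidate with its hyper-parameters and mean CV
#'   metrics.
#' @method tidy acp_grid
#' @export
tidy.acp_grid <- function(x, ...) x$results

#' One-row summary of a grid-search result
#'
#' @inheritParams tidy.acp_grid
#' @return The winning candidate's row.
#' @method glance acp_grid
#' @export
glance.acp_grid <- function(x, ...) {
  x$results[x$best_index, ]
}

#' Tidy a trained model's training log
#'
#' @param x An `acp_model`.
#' @param ... Unused.
#' @return Tibble with `epoch` and mean `loss`.
#' @method tidy acp_model
#' @export
tidy.acp_model <- function(x, ...) x$training_log

#' One-row summary of a model
#'
#' @inheritParams tidy.acp_model
#' @return Tibble with the architecture, scheme, sizes, epochs and final
#'   training loss.
#' @method glance acp_model
#' @export
glance.acp_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$config$architecture,
    scheme = x$config$scheme$name,
    n_units = x$config$n_units,
    dense_units = x$config$dense_units,
    epochs = x$config$epochs,
    trained = x$trained,
    final_loss = if (nrow(x$training_log)) {
      x$training_log$loss[nrow(x$training_log)]
    } else {
      NA_real_
    }
  )
}

#' Tidy an attribution report
#'
#' @param x An `acp_attribution`.
#' @param ... Unused.
#' @return Long tibble `(id, position, channel, phi)`; see
#'   [attribution_long()].
#' @method tidy acp_attribution
#' @export
tidy.acp_attribution <- function(x, ...) attribution_long(x)

#' One-row-per-channel summary of an attribution report
#'
#' @inheritParams tidy.acp_attribution
#' @return The channel-importance ranking tibble.
#' @method glance acp_attribution
#' @export
glance.acp_attribution <- function(x, ...) x$importance
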