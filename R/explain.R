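## Shapley-value attributions, channel importance, and PCA projection of
## learned features.
##
## The estimator is model-agnostic permutation Shapley with background-mean
## replacement: an "absent" feature takes the background-average value. For
## one permutation the per-feature increments telescope, so the base value
## (the prediction at the background average) plus the attributions equals
## the model output for every explained sample *exactly*, independent of the
## number of permutations; more permutations only reduce the variance of the
## per-feature split.

#' Permutation Shapley values for a black-box function
#'
#' Estimates Shapley values of `f` at `x` by sampling feature permutations;
#' features absent from a coalition are set to the background column means.
#'
#' @param f A function taking a numeric matrix (rows = inputs) and returning
#'   a numeric vector of outputs.
#' @param x Numeric feature vector to explain (length M).
#' @param background Numeric matrix (rows = background samples, M columns),
#'   or a single numeric vector.
#' @param n_perm Number of sampled permutations.
#' @param seed Integer seed.
#' @return List with `phi` (length-M attributions), `phi0` (prediction at the
#'   background mean) and `fx` (the prediction being explained;
#'   `phi0 + sum(phi) == fx` up to float roundoff).
#' @export
#' @examples
#' f <- function(X) X[, 1] + 2 * X[, 2]
#' shapley_permutation(f, c(3, 1, 5), background = rep(0, 3), n_perm = 10, seed = 1)$phi
shapley_permutation <- function(f, x, background, n_perm = 10L, seed = 1L) {
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  if (nrow(background) == 0L) abort_validation("background must be non-empty")
  if (ncol(background) != length(x)) {
    abort_validation("background width must match length(x)")
  }
  M <- length(x)
  bg <- colMeans(background)
  phi <- numeric(M)
  perms <- with_seed(seed, replicate(n_perm, sample.int(M), simplify = FALSE))
  for (ord in perms) {
    Z <- matrix(bg, M + 1L, M, byrow = TRUE)
    for (k in seq_len(M)) {
      Z[(k + 1L):(M + 1L), ord[k]] <- x[ord[k]]
    }
    v <- f(Z)
    phi[ord] <- phi[ord] + diff(v)
  }
  phi <- phi / n_perm
  v_ends <- unname(f(unname(rbind(bg, x))))
  list(phi = phi, phi0 = v_ends[1L], fx = v_ends[2L])
}

#' Exact Shapley values by coalition enumeration
#'
#' Brute-force Shapley values over all 2^M coalitions, with absent features
#' set to the background column means. Exponential in M; intended as an
#' independent oracle for small feature counts.
#'
#' @inheritParams shapley_permutation
#' @return As [shapley_permutation()].
#' @export
shapley_exact <- function(f, x, background) {
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  M <- length(x)
  if (M > 15L) abort_validation("shapley_exact() is limited to M <= 15 features")
  bg <- colMeans(background)
  n_sets <- 2L^M
  ## coalition matrix: row s = membership pattern of subset s - 1
  member <- matrix(FALSE, n_sets, M)
  for (j in seq_len(M)) {
    member[, j] <- bitwAnd(seq_len(n_sets) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  Z <- matrix(bg, n_sets, M, byrow = TRUE)
  for (j in seq_len(M)) Z[member[, j], j] <- x[j]
  v <- f(Z)
  sizes <- rowSums(member)
  phi <- numeric(M)
  for (j in seq_len(M)) {
    without <- which(!member[, j])
    with_j <- without + bitwShiftL(1L, j - 1L)
    s <- sizes[without]
    w <- factorial(s) * factorial(M - s - 1L) / factorial(M)
    phi[j] <- sum(w * (v[with_j] - v[without]))
  }
  list(phi = phi, phi0 = unname(v[1L]), fx = unname(v[n_sets]))
}

#' Shapley attributions for a trained peptide classifier
#'
#' Explains the model's ACP-class probability per (position, channel) cell of
#' the encoded input. Absent cells are replaced by the background average of
#' the encoded background peptides. Fixed encodings only: the trainable
#' embedding scheme has no fixed per-input feature values to attribute to.
#'
#' @param model A trained `acp_model` (scheme other than `"embedding"`).
#' @param samples Peptide tibble to explain.
#' @param background Peptide tibble of background (e.g. training) sequences;
#'   at most `max_background` (default 100) are used, drawn with a fixed
#'   internal seed when more are supplied.
#' @param n_perm Permutations per explained sample.
#' @param seed Integer seed.
#' @param max_background Cap on background rows.
#' @return An object of class `acp_attribution`: list with
#'   * `phi` -- `n x lmax x d` array of Shapley values;
#'   * `phi0` -- base value (prediction at the background average);
#'   * `fx` -- explained predictions, `phi0 + rowSums(phi) == fx`;
#'   * `ids`, `channels`;
#'   * `importance` -- per-channel mean `|phi|` ranking tibble.
#' @export
shapley_attributions <- function(model, samples, background, n_perm = 2L,
                                 seed = 1L, max_background = 100L) {
  stopifnot(inherits(model, "acp_model"))
  config <- model$config
  if (config$scheme$name == "embedding") {
    abort_validation(
      "attributions are defined for fixed encodings; the embedding scheme has no fixed feature values"
    )
  }
  samples <- validate_peptides(samples, lmax = config$lmax)
  background <- validate_peptides(background, lmax = config$lmax)
  if (nrow(background) == 0L) abort_validation("background must be non-empty")
  if (nrow(background) > max_background) {
    keep <- with_seed(20231L, sample.int(nrow(background), max_background))
    background <- background[keep, ]
  }
  L <- config$lmax
  d <- config$scheme$d
  Xs <- encode_dataset(samples, config$scheme, lmax = L)
  Xb <- encode_dataset(background, config$scheme, lmax = L)
  bg_flat <- matrix(Xb, nrow(background), L * d)  # column = pos + (chan-1)L
  f <- function(Z) {
    out <- numeric(nrow(Z))
    for (s in seq(1L, nrow(Z), by = 512L)) {
      rows <- s:min(s + 512L - 1L, nrow(Z))
      Xc <- array(Z[rows, , drop = FALSE], c(length(rows), L, d))
      fw <- forward_pass(model$params, config, Xc, cache = FALSE)
      out[rows] <- fw$probs[, 2L]
    }
    out
  }
  n <- nrow(samples)
  phi <- array(0, c(n, L, d))
  phi0 <- NA_real_
  fx <- numeric(n)
  for (i in seq_len(n)) {
    x_flat <- as.vector(matrix(Xs[i, , ], L, d))
    res <- shapley_permutation(f, x_flat, bg_flat,
      n_perm = n_perm, seed = seed + i
    )
    phi[i, , ] <- matrix(res$phi, L, d)
    phi0 <- res$phi0
    fx[i] <- res$fx
  }
  report <- structure(list(
    phi = phi, phi0 = phi0, fx = fx, ids = samples$id,
    channels = config$scheme$channel_names
  ), class = "acp_attribution")
  report$importance <- channel_importance(report)
  report
}

#' @export
print.acp_attribution <- function(x, ...) {
  cat(sprintf(
    "<acp_attribution> %d sample(s), base value %.4f; top channels: %s\n",
    length(x$ids), x$phi0,
    paste(head(x$importance$channel, 3L), collapse = ", ")
  ))
  invisible(x)
}

#' Channel importance ranking
#'
#' Importance of a channel is the mean of `|phi|` over all explained samples
#' and all sequence positions; channels are ranked in descending order, ties
#' broken by channel index.
#'
#' @param report An `acp_attribution`.
#' @return A tibble with columns `channel`, `importance`, `rank`.
#' @export
channel_importance <- function(report) {
  stopifnot(inherits(report, "acp_attribution"))
  imp <- apply(abs(report$phi), 3L, mean)
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(
    channel = report$channels[ord],
    importance = imp[ord],
    rank = seq_along(ord)
  )
}

#' Long-format export of an attribution report
#'
#' @param report An `acp_attribution`.
#' @return Tibble with columns `id`, `position`, `channel`, `phi`.
#' @export
attribution_long <- function(report) {
  stopifnot(inherits(report, "acp_attribution"))
  dm <- dim(report$phi)
  tibble::tibble(
    id = rep(report$ids, times = dm[2L] * dm[3L]),
    position = rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]),
    channel = rep(report$channels, each = dm[1L] * dm[2L]),
    phi = as.vector(report$phi)
  )
}

#' PCA projection of feature vectors
#'
#' Centers the features and projects them onto the top `k` principal axes;
#' used to visualize penultimate-layer features in 2-D.
#'
#' @param features Numeric matrix (samples x features) or data frame.
#' @param k Number of components (default 2).
#' @return An object of class `acp_projection`: list with `coordinates`
#'   (tibble `PC1..PCk`, plus `id` when rownames exist) and
#'   `explained_variance_ratio` (length k, non-increasing, sums to <= 1).
#' @export
#' @examples
#' f <- cbind(rnorm(50, sd = 2), rnorm(50, sd = 1))
#' pca_project(f)$explained_variance_ratio
pca_project <- function(features, k = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < k || ncol(features) < k) {
    abort_validation("need at least k samples and k feature columns")
  }
  if (all(apply(features, 2L, stats::var) < .Machine$double.eps)) {
    abort_validation("degenerate input: all feature vectors are identical")
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(as.data.frame(pc$x[, seq_len(k), drop = FALSE]))
  if (!is.null(rownames(features))) {
    coords <- dplyr::bind_cols(tibble::tibble(id = rownames(features)), coords)
  }
  structure(list(
    coordinates = coords,
    explained_variance_ratio = ratio[seq_len(k)]
  ), class = "acp_projection")
}
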