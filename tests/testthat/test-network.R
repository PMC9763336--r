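test_that("model building is deterministic and shapes follow the config", {
  cfg <- model_config(
    scheme = "mix", architecture = "selfatt", n_units = 6L,
    dense_units = 5L, epochs = 1L, seed = 42L, attention_width = 4L
  )
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  # attention parameters: W in R^{2n}, b in R^{Lmax}
  expect_length(m1$params$att$W, 12L)
  expect_length(m1$params$att$b, 50L)
  expect_equal(dim(m1$params$sa$Wt), c(12L, 4L))
  expect_equal(dim(m1$params$dense$W2), c(5L, 2L))

  basic <- build_model(model_config(n_units = 4L, dense_units = 3L, seed = 1L))
  expect_null(basic$params$sa)
  expect_null(basic$params$att)

  emb <- build_model(model_config(scheme = "embedding", n_units = 4L, seed = 1L))
  expect_equal(dim(emb$params$emb), c(20L, 36L))

  expect_error(model_config(epochs = 0), class = "acplearn_validation_error")
  expect_error(model_config(n_units = 0), class = "acplearn_validation_error")
})

test_that("attention pooling equals its direct-summation oracle", {
  set.seed(101)
  # uniform limit: constant scores average the rows
  h <- matrix(rnorm(5 * 4), 5, 4)
  res <- attention_pool(h, W = rep(0, 4), b = rep(0, 5))
  expect_equal(res$alpha, rep(1 / 5, 5))
  expect_equal(res$pooled, colMeans(h))

  # selection limit: a dominant score picks out one row
  res_sel <- attention_pool(h, W = rep(0, 4), b = c(0, 1e4, 0, 0, 0))
  expect_equal(res_sel$pooled, h[2L, ], tolerance = 1e-9)

  # brute-force direct summation on random instances
  for (i in 1:100) {
    L <- sample(2:8, 1)
    D <- sample(2:6, 1)
    h <- matrix(rnorm(L * D), L, D)
    W <- rnorm(D)
    b <- rnorm(L)
    res <- attention_pool(h, W, b)
    e <- as.numeric(h %*% W) + b
    expected <- rep(0, D)
    denom <- sum(exp(e))
    for (j in seq_len(L)) expected <- expected + exp(e[j]) * h[j, ] / denom
    expect_equal(res$pooled, expected, tolerance = 1e-9)
    expect_equal(sum(res$alpha), 1, tolerance = 1e-6)
  }
  expect_error(attention_pool(h, W = rep(0, 3), b = rep(0, 2)),
               class = "acplearn_validation_error")
})

test_that("self-attention matches a 4-term hand expansion on two positions", {
  # L = 2, D = 2, score width 2: expand every (t, t') pair by hand
  x <- matrix(c(0.5, -1.0, 0.25, 0.75), 2, 2)
  p <- list(
    Wt = matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2),
    Wx = matrix(c(-0.5, 0.2, 0.6, -0.1), 2, 2),
    bt = c(0.05, -0.15),
    wa = c(0.7, -0.3),
    ba = 0.2
  )
  sig <- function(v) 1 / (1 + exp(-v))
  e <- matrix(0, 2, 2)
  for (t in 1:2) {
    for (tp in 1:2) {
      hid <- tanh(as.numeric(x[t, ] %*% p$Wt) + as.numeric(x[tp, ] %*% p$Wx) + p$bt)
      e[t, tp] <- sig(sum(p$wa * hid) + p$ba)
    }
  }
  a <- t(apply(e, 1L, function(r) exp(r) / sum(exp(r))))
  l_expected <- a %*% x

  res <- self_attention(x, p)
  expect_equal(res$attention, a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$out, l_expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("self-attention is uniform for identical positions and rows normalize", {
  set.seed(7)
  D <- 4L
  p <- list(
    Wt = matrix(rnorm(D * 3), D, 3), Wx = matrix(rnorm(D * 3), D, 3),
    bt = rnorm(3), wa = rnorm(3), ba = 0.1
  )
  const_row <- rnorm(D)
  x_const <- matrix(rep(const_row, each = 6), 6, D)
  res <- self_attention(x_const, p)
  expect_equal(res$attention, matrix(1 / 6, 6, 6), tolerance = 1e-12)
  for (t in 1:6) expect_equal(res$out[t, ], const_row, tolerance = 1e-12)

  x_rand <- matrix(rnorm(6 * D), 6, D)
  res2 <- self_attention(x_rand, p)
  expect_equal(unname(rowSums(res2$attention)), rep(1, 6), tolerance = 1e-6)
})

test_that("forward outputs are probability pairs, stateless and batch-invariant", {
  cfg <- model_config(n_units = 6L, dense_units = 5L, epochs = 1L, seed = 12L)
  model <- build_model(cfg)
  peps <- peptide_tbl(
    c("a", "b", "a2", "c"),
    c("KKKRWFY", "DDDEEAG", "KKKRWFY", "ACDEFGHIKLMNPQRSTVWY")
  )
  preds <- predict(model, peps)
  expect_equal(preds$p_acp + preds$p_non_acp, rep(1, 4), tolerance = 1e-6)
  expect_true(all(preds$p_acp >= 0 & preds$p_acp <= 1))
  # duplicated peptide in one batch scores identically
  expect_equal(preds$p_acp[1L], preds$p_acp[3L])
  # batch of one vs batch of many
  solo <- predict(model, peps[4L, ])
  expect_equal(solo$p_acp, preds$p_acp[4L], tolerance = 1e-6)

  sa_model <- build_model(model_config(
    architecture = "selfatt", n_units = 4L, dense_units = 5L,
    epochs = 1L, seed = 12L, attention_width = 3L
  ))
  sa_preds <- predict(sa_model, peps)
  expect_equal(sa_preds$p_acp + sa_preds$p_non_acp, rep(1, 4), tolerance = 1e-6)
  expect_equal(sa_preds$p_acp[1L], sa_preds$p_acp[3L])
})

test_that("penultimate features have dense_units width and are reproducible", {
  cfg <- model_config(n_units = 5L, dense_units = 7L, epochs = 1L, seed = 2L)
  model <- build_model(cfg)
  peps <- peptide_tbl(c("a", "b", "a2"), c("KKKK", "DDDD", "KKKK"))
  f1 <- penultimate_features(model, peps)
  expect_equal(dim(f1), c(3L, 7L))
  expect_equal(f1["a", ], f1["a2", ])
  f2 <- penultimate_features(model, peps)
  expect_identical(f1, f2)
})

test_that("serialization round-trips models with bit-identical predictions", {
  fit <- train_model(tiny_config(epochs = 2L), make_separable(4L))
  peps <- make_separable(4L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(fit, peps), predict(back, peps))
  expect_error(read_model(file.path(tempdir(), "nope.rds")),
               class = "acplearn_io_error")
})
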