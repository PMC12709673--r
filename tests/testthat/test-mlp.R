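test_that("stratum weights follow the square-root inverse-frequency rule", {
  counts <- c(n_0 = 100L, n_1 = 100L, n_2 = 0L, n_3 = 25L)
  w <- compute_stratum_weights(counts)
  expect_equal(unname(w), c(1, 1, 0, 2))

  w2 <- compute_stratum_weights(c(n_0 = 400L, n_1 = 100L))
  expect_equal(unname(w2[2]), 2)

  w7 <- compute_stratum_weights(c(n_0 = 1e6, n_7 = 530))
  expect_equal(unname(w7[2]), sqrt(1e6 / 530))
  expect_equal(unname(w7[2]), 43.43722, tolerance = 1e-5)

  expect_error(compute_stratum_weights(c(n_0 = 0L, n_1 = 5L)), "n_0")
})

test_that("the weighted sampler hits the expected stratum shares", {
  k <- c(rep(0L, 100), rep(1L, 100))
  w <- c(1, 2, rep(0, 6))
  idx <- weighted_sample_idx(k, w, n_draws = 1e5, seed = 4)
  share1 <- mean(k[idx] == 1L)
  se <- sqrt(2 / 3 * 1 / 3 / 1e5)
  expect_lt(abs(share1 - 2 / 3), 3 * se)
  ## deterministic given seed; default draw count is one epoch
  expect_identical(weighted_sample_idx(k, w, seed = 4),
                   weighted_sample_idx(k, w, seed = 4))
  expect_length(weighted_sample_idx(k, w, seed = 1), length(k))
  expect_error(weighted_sample_idx(k, rep(0, 8)), "zero")
})

test_that("training solves a separable toy problem", {
  v <- sample_variants(10, seed = 20)
  ## one target active: label = has D at position 1
  y <- matrix(0L, 10, 7)
  y[, 1] <- as.integer(substr(v, 1, 1) %in% make_alphabet()$letters[1:9])
  if (sum(y[, 1]) %in% c(0, 10)) y[1:5, 1] <- 1 - y[1:5, 1]
  x <- embed_sequences(v, embedding_scheme("ONEHOT"))
  cfg <- mlp_config(hidden_sizes = c(32L, 32L), learning_rate = 1e-2,
                    epochs = 50L, batch_size = 10L, output_dim = 7L,
                    seed = 2)
  model <- mlp_train(x, y, config = cfg)
  pred <- predict(model, x) >= 0.5
  expect_equal(f1_score(y[, 1], pred[, 1]), 1)
})

test_that("training is deterministic for a fixed seed", {
  v <- sample_variants(200, seed = 21)
  y <- matrix(rbinom(200 * 7, 1, 0.2), 200, 7)
  x <- embed_sequences(v, embedding_scheme("VHSE8"))
  cfg <- tiny_mlp_config(seed = 9)
  m1 <- mlp_train(x, y, config = cfg)
  m2 <- mlp_train(x, y, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss, m2$loss)
  m3 <- mlp_train(x, y, config = tiny_mlp_config(seed = 10))
  expect_false(identical(m1$params, m3$params))
})

test_that("a zeroed output layer predicts probability one half", {
  v <- sample_variants(5, seed = 22)
  x <- embed_sequences(v, embedding_scheme("BLOSUM50"))
  cfg <- tiny_mlp_config()
  model <- mlp_train(x, matrix(0L, 5, 7), k = rep(0L, 5), config = cfg)
  nl <- length(model$params)
  model$params[[nl]]$W[] <- 0
  model$params[[nl]]$b[] <- 0
  expect_equal(unname(predict(model, x)), matrix(0.5, 5, 7))
})

test_that("batch prediction equals per-item prediction", {
  v <- sample_variants(50, seed = 23)
  y <- matrix(rbinom(50 * 7, 1, 0.3), 50, 7)
  x <- embed_sequences(v, embedding_scheme("BLOSUM50"))
  model <- mlp_train(x, y, config = tiny_mlp_config())
  batch <- predict(model, x)
  single <- t(vapply(seq_len(50), function(i) {
    predict(model, x[i, , drop = FALSE])[1, ]
  }, numeric(7)))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_true(all(batch > 0 & batch < 1))
  expect_error(predict(model, x[, 1:10]), "expects")
})

test_that("sampler frequencies converge to the weighted composition", {
  counts <- c(n_0 = 500L, n_1 = 300L, n_2 = 150L, n_3 = 0L, n_4 = 0L,
              n_5 = 0L, n_6 = 0L, n_7 = 50L)
  k <- rep(c(0L, 1L, 2L, 7L), times = counts[c(1, 2, 3, 8)])
  w <- compute_stratum_weights(counts)
  idx <- weighted_sample_idx(k, w, n_draws = 1e5, seed = 6)
  obs <- table(factor(k[idx], levels = c(0, 1, 2, 7)))
  expected <- w[c(1, 2, 3, 8)] * counts[c(1, 2, 3, 8)]
  p <- chisq.test(obs, p = expected / sum(expected))$p.value
  expect_gt(p, 0.01)
})
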