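test_that("masking deletes the right positions", {
  expect_equal(mask_sequences("DSWLAG", "a99"), "SWLAG")
  expect_equal(mask_sequences("DSWLAG", "b100"), "DSWLA")
  expect_equal(mask_sequences("DSWLAG", "alpha"), "LAG")
  expect_equal(mask_sequences("DSWLAG", "beta"), "DSW")
  expect_error(mask_sequences("DSWLAG", "gamma"), "unknown mask")
  specs <- mask_specs()
  expect_length(specs, 8)
  expect_equal(lengths(specs)[c("alpha", "beta")], c(alpha = 3L, beta = 3L))
})

test_that("masked collisions keep every row with its own labels", {
  v <- c("DSWLAG", "ESWLAG")  # differ only at a99
  m <- mask_sequences(v, "a99")
  expect_equal(m, c("SWLAG", "SWLAG"))
  expect_length(m, 2)
  ## collision-count oracle on a random set
  v <- sample_variants(500, seed = 50)
  m <- mask_sequences(v, "b99")
  expect_length(m, 500)
  expect_equal(sum(duplicated(m)), 500 - length(unique(m)))
})

test_that("masked input dimension is (6 - d) x per-residue dim", {
  v <- sample_variants(5, seed = 51)
  for (scheme in c("BLOSUM50", "VHSE8", "ONEHOT")) {
    sc <- embedding_scheme(scheme)
    for (mask in names(mask_specs())) {
      d <- length(mask_specs()[[mask]])
      x <- embed_sequences(mask_sequences(v, mask), sc)
      expect_equal(ncol(x), (6 - d) * sc$per_residue_dim)
    }
  }
})

test_that("energy correlation follows Spearman on shared masks", {
  imp <- list(summary = data.frame(
    mask = c("a99", "a100", "a101", "b98", "b99", "b100", "alpha", "beta"),
    mean_delta_f1 = c(-0.5, -0.1, -0.4, -0.2, -0.02, -0.05, -0.6, -0.15),
    mean_delta_auprc = c(-0.4, -0.08, -0.3, -0.15, -0.01, -0.04, -0.5, -0.1)))

  ## monotone transform of the deltas: perfect negative rank correlation
  en <- data.frame(mask = imp$summary$mask,
                   delta_isc = -imp$summary$mean_delta_f1 * 3 + 1)
  res <- correlate_energy(imp, en)
  expect_equal(res$rho, -1)

  ## brute-force rank formula oracle on untied 8-point data
  set.seed(52)
  en$delta_isc <- rnorm(8)
  res <- correlate_energy(imp, en)
  m <- merge(imp$summary, en, by = "mask")
  expect_equal(res$rho, oracle_spearman(m$mean_delta_f1, m$delta_isc),
               tolerance = 1e-12)

  ## tie-degenerate energies
  en$delta_isc <- rep(1, 8)
  res <- correlate_energy(imp, en)
  expect_equal(res$rho, 0)
  expect_equal(res$p_value, 1)

  expect_error(correlate_energy(imp, en[1:2, ]), "at least 3")
})

test_that("the packaged synthetic energy table loads and correlates", {
  path <- system.file("extdata", "synthetic_delta_isc.tsv",
                      package = "kbindr")
  expect_true(nzchar(path))
  en <- read_energy_tsv(path)
  expect_setequal(en$mask, names(mask_specs()))
  imp <- list(summary = data.frame(
    mask = names(mask_specs()),
    mean_delta_f1 = c(-0.5, -0.1, -0.4, -0.2, -0.02, -0.05, -0.6, -0.15)))
  res <- correlate_energy(imp, en)
  expect_true(res$rho <= 1 && res$rho >= -1)
  expect_equal(res$n, 8)
})

test_that("chain comparison is a paired signed-rank test on chain deltas", {
  deltas <- expand.grid(mask = c("alpha", "beta"), seed = 1, fold = 1:4,
                        stratum = "all", target = c("Tax", "HUD"),
                        stringsAsFactors = FALSE)
  set.seed(53)
  deltas$delta_f1 <- ifelse(deltas$mask == "alpha",
                            -0.4 + rnorm(nrow(deltas), 0, 0.01),
                            -0.1 + rnorm(nrow(deltas), 0, 0.01))
  deltas$delta_auprc <- deltas$delta_f1
  imp <- list(deltas = deltas)
  res <- chain_comparison(imp)
  expect_lt(res$p_value, 0.05)
  ## flipped direction is not significant under "less"
  imp$deltas$delta_f1 <- -imp$deltas$delta_f1
  expect_gt(chain_comparison(imp)$p_value, 0.5)
})

test_that("masking an irrelevant position barely changes performance", {
  ## landscape whose b99 weight is exactly zero
  w <- c(a99 = 1, a100 = 0.4, a101 = 0.7, b98 = 0.5, b99 = 0, b100 = 0.25)
  ls <- make_landscape(position_weights = w)
  v <- sample_variants(6000, seed = 54)
  gt <- ground_truth_profiles(v, ls)
  y <- as.matrix(gt[, ls$targets]) * 1L
  imp <- masked_importance(gt$variant, y, gt$k,
                           config = desk_mlp_config(seed = 1),
                           n_folds = 4, seeds = 1, folds_run = 1,
                           masks = c("b99", "a99"))
  s <- imp$summary
  expect_lt(abs(s$mean_delta_f1[s$mask == "b99"]), 0.06)
  ## while the top-weight position clearly matters
  expect_lt(s$mean_delta_f1[s$mask == "a99"], -0.1)
})
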