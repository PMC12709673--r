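## fixture: 10 variants with printed round-3 counts for one target
binding_fixture <- function() {
  v <- sample_variants(10, seed = 77)
  counts <- data.frame(
    variant = rep(v, 2),
    rep = rep(1:2, each = 10),
    reads = c(5, 2, 0, 1, 9, 0, 3, 1, 0, 7,   # replicate 1
              2, 0, 4, 1, 1, 0, 0, 2, 6, 3))  # replicate 2
  pan <- data.frame(
    target = "Tax", replicate = counts$rep, round = 3L,
    cdr3_alpha = substr(counts$variant, 1, 3),
    cdr3_beta = substr(counts$variant, 4, 6),
    reads = counts$reads)
  pan[pan$reads > 0, ]
}

test_that("binder calling requires presence in both replicates", {
  pan <- binding_fixture()
  v <- sample_variants(10, seed = 77)
  got <- call_binders(pan, "Tax")
  ## brute-force row scan oracle
  r1 <- pan[pan$replicate == 1, ]
  r2 <- pan[pan$replicate == 2, ]
  expected <- sort(intersect(paste0(r1$cdr3_alpha, r1$cdr3_beta),
                             paste0(r2$cdr3_alpha, r2$cdr3_beta)))
  expect_equal(got, expected)
  ## presence/absence specifics: v[1] (5,2) in, v[2] (2,0) out
  expect_true(v[1] %in% got)
  expect_false(v[2] %in% got)
})

test_that("raising min_reads never adds binders", {
  pan <- binding_fixture()
  sets <- lapply(1:5, function(m) call_binders(pan, "Tax", min_reads = m))
  for (i in 2:5) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  ## and is strictly monotone somewhere on this fixture
  expect_lt(length(sets[[5]]), length(sets[[1]]))
})

test_that("a missing replicate is reported by name", {
  pan <- binding_fixture()
  expect_error(call_binders(pan[pan$replicate == 1, ], "Tax"),
               "replicate 2")
  expect_error(call_binders(pan, "HUD"), "HUD")
})

test_that("profiles assign S and k and strata partition the universe", {
  sets <- list(Tax = c("AAAAAA", "DDDDDD"), HUD = c("DDDDDD"),
               BENE = character(0), F = c("EEEEEE"), TY = character(0),
               TM = character(0), HOM = c("DDDDDD"))
  universe <- c("AAAAAA", "DDDDDD", "EEEEEE", "GGGGGG")
  prof <- profile_variants(sets, universe)
  expect_equal(prof$k[prof$variant == "AAAAAA"], 1L)
  expect_equal(prof$k[prof$variant == "DDDDDD"], 3L)
  expect_equal(prof$k[prof$variant == "GGGGGG"], 0L)
  counts <- stratum_counts(prof)
  expect_equal(sum(counts), length(universe))
  expect_equal(unname(counts[1:4]), c(1L, 2L, 0L, 1L))
})

test_that("S-class sizes within each k sum to the stratum count", {
  set.seed(42)
  b <- matrix(runif(300 * 7) < 0.25, 300, 7)
  colnames(b) <- c("Tax", "HUD", "BENE", "F", "TY", "TM", "HOM")
  prof <- make_profiles(b)
  counts <- stratum_counts(prof)
  for (k in 0:7) {
    classes <- apply(b, 1, function(r) paste(which(r), collapse = ","))
    sel <- prof$k == k
    expect_equal(sum(sel), unname(counts[k + 1]))
    if (k %in% 1:2) {
      sizes <- table(classes[sel])
      expect_equal(sum(sizes), unname(counts[k + 1]))
    }
  }
})

test_that("cross-reactivity null probability matches the closed form", {
  ## all marginals 0.1: q = 1 - 0.9^7 - 7 * 0.1 * 0.9^6
  q_expected <- 1 - 0.9^7 - 7 * 0.1 * 0.9^6
  set.seed(1)
  b <- matrix(FALSE, 100, 7)
  colnames(b) <- c("Tax", "HUD", "BENE", "F", "TY", "TM", "HOM")
  ## engineer exactly 10 bound per target, 30 variants with k >= 2
  b[1:30, 1:2] <- TRUE
  prof <- make_profiles(b)
  ct <- crossreactivity_test(prof)
  expect_equal(ct$marginal_rates[["Tax"]], 0.3)
  ## check the lattice enumeration against the closed form directly
  expect_equal(kbindr:::prob_k_ge_2(rep(0.1, 7)), q_expected,
               tolerance = 1e-12)
  ## p-value equals the binomial tail sum
  q <- ct$q_null
  manual_p <- sum(dbinom(ct$observed:ct$n, ct$n, q))
  expect_equal(ct$p_value, manual_p, tolerance = 1e-10)
})

test_that("degenerate all-zero marginals give q = 0 and p = 0 when observed", {
  b <- matrix(FALSE, 50, 7)
  colnames(b) <- c("Tax", "HUD", "BENE", "F", "TY", "TM", "HOM")
  prof <- make_profiles(b)
  prof$k[1] <- 2L  # an impossible observation under this null
  ct <- crossreactivity_test(prof)
  expect_equal(ct$q_null, 0)
  expect_equal(ct$p_value, 0)
})
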