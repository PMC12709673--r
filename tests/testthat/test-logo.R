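test_that("identical sequences give maximal information content", {
  logo <- build_logo(rep("DSWLAG", 25))
  expect_equal(unname(logo$ic), rep(log2(20), 6), tolerance = 1e-12)
  expect_true(all(abs(rowSums(logo$freq) - 1) < 1e-9))
})

test_that("uniform residue usage gives zero information at basis 19", {
  ab <- make_alphabet()
  v <- vapply(1:19, function(i) paste(rep(ab$letters[i], 6), collapse = ""),
              character(1))
  logo <- build_logo(v, basis = 19L)
  expect_equal(unname(logo$ic), rep(0, 6), tolerance = 1e-12)
  ## with the default 20 ceiling the same data has log2(20/19) bits
  logo20 <- build_logo(v)
  expect_equal(unname(logo20$ic), rep(log2(20) - log2(19), 6),
               tolerance = 1e-12)
})

test_that("frequencies and entropy match a hand computation", {
  v <- c("DSWLAG", "DSWLAG", "DAWLAG", "ESWLAG")
  logo <- build_logo(v)
  expect_equal(logo$freq["a99", "D"], 0.75)
  expect_equal(logo$freq["a99", "E"], 0.25)
  h1 <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(unname(logo$ic[["a99"]]), log2(20) - h1, tolerance = 1e-12)
  expect_equal(unname(logo$ic[["a101"]]), log2(20), tolerance = 1e-12)
  expect_error(build_logo(character(0)), "zero sequences")
})

test_that("logo grid keys cover nonempty 1- and 2-binding classes only", {
  b <- matrix(FALSE, 8, 3, dimnames = list(NULL, c("Tax", "HUD", "BENE")))
  b[1, 1] <- TRUE                 # Tax only
  b[2, 2] <- TRUE                 # HUD only
  b[3, c(1, 2)] <- TRUE           # Tax+HUD
  b[4, 1:3] <- TRUE               # k=3, not in the grid
  prof <- make_profiles(b)
  prof$variant <- sample_variants(8, seed = 3)
  logos <- logo_grid(prof)
  expect_setequal(names(logos), c("Tax", "HUD", "Tax+HUD"))
  ## at most C(3,1) + C(3,2) = 6 classes possible
  expect_lte(length(logos), 6L)
})

test_that("on the default landscape 2-binding logos carry more alpha-position
          information than 1-binding logos", {
  ls <- make_landscape()
  ok <- 0
  for (seed in 1:3) {
    v <- sample_variants(5e4, seed = 200 + seed)
    prof <- ground_truth_profiles(v, ls)
    names(prof)[1] <- "variant"
    logos <- logo_grid(prof)
    k1 <- names(logos)[!grepl("\\+", names(logos))]
    k2 <- names(logos)[grepl("\\+", names(logos))]
    alpha_ic <- function(nms) {
      mean(vapply(nms, function(n) mean(logos[[n]]$ic[1:3]), numeric(1)))
    }
    if (length(k1) && length(k2) && alpha_ic(k2) > alpha_ic(k1)) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("diagnostics count unique variants and top-100 share", {
  ## cell with exactly 100 variants: top share is 1
  v <- sample_variants(100, seed = 15)
  pan <- data.frame(target = "Tax", replicate = 1L, round = 3L,
                    cdr3_alpha = substr(v, 1, 3),
                    cdr3_beta = substr(v, 4, 6),
                    reads = rpois(100, 10) + 1L)
  d <- panning_diagnostics(pan)
  expect_equal(d$n_unique, 100L)
  expect_equal(d$top_share, 1)

  ## brute-force sort-and-sum oracle on a larger cell
  v <- sample_variants(250, seed = 16)
  set.seed(16)
  reads <- rpois(250, 5) + 1L
  pan <- data.frame(target = "HUD", replicate = 2L, round = 1L,
                    cdr3_alpha = substr(v, 1, 3),
                    cdr3_beta = substr(v, 4, 6), reads = reads)
  d <- panning_diagnostics(pan)
  expect_equal(d$top_share, sum(sort(reads, decreasing = TRUE)[1:100]) /
                 sum(reads))
  expect_true(d$top_share >= 0 && d$top_share <= 1)
})

test_that("ties at the top-100 boundary resolve deterministically", {
  v <- sort(sample_variants(150, seed = 17))
  pan <- data.frame(target = "Tax", replicate = 1L, round = 2L,
                    cdr3_alpha = substr(v, 1, 3),
                    cdr3_beta = substr(v, 4, 6),
                    reads = rep(1L, 150))
  d1 <- panning_diagnostics(pan)
  d2 <- panning_diagnostics(pan[sample(150), ])
  expect_equal(d1$top_share, d2$top_share)
  expect_equal(d1$top_share, 100 / 150)
})
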