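# Brute-force reference implementations used to cross-check the package's
# statistics, plus small fixture builders.  These oracles are deliberately
# written from the defining formulas, independent of the code under test.

oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_dunn_z <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt(sig2 * (1 / n1 + 1 / n2))
}

# Mann-Whitney U by exhaustive pair counting (ties count 1/2).
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Wilcoxon signed-rank statistic: sum of ranks of |d| over positive d.
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  sum(rank(abs(d))[d > 0])
}

# Spearman rho via the classical formula (valid for untied data).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Average precision as the mean of precision-at-rank over positives
# (requires unique scores).
oracle_ap <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  t <- as.logical(truth)[ord]
  ranks <- which(t)
  mean(vapply(ranks, function(r) sum(t[1:r]) / r, numeric(1)))
}

# Tiny two-target landscape-independent profile table builder.
make_profiles <- function(bound, targets = colnames(bound)) {
  df <- data.frame(variant = sprintf("v%03d", seq_len(nrow(bound))),
                   bound, check.names = FALSE, stringsAsFactors = FALSE)
  df$k <- as.integer(rowSums(bound))
  df
}

# Shared small config for fast model fits in unit tests.
tiny_mlp_config <- function(seed = 1L) {
  mlp_config(hidden_sizes = c(16L, 16L), learning_rate = 1e-2,
             epochs = 5L, batch_size = 256L, seed = seed)
}

# Desk-scale training configuration used for the synthetic-landscape
# experiments (see the methods vignette).
desk_mlp_config <- function(seed = 1L) {
  mlp_config(hidden_sizes = c(128L, 128L), learning_rate = 1e-3,
             seed = seed)
}

# The generator's default position-weight ordering, most important first.
TRUE_POSITION_ORDER <- c("a99", "a101", "b98", "a100", "b100", "b99")
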