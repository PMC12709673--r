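#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Runs the rank-based Kruskal-Wallis test (tie-corrected H, chi-square
#' p-value) and reports the epsilon-squared effect size
#' `eps2 = H / (n - 1)`, the proportion of rank variance explained by
#' group membership.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor (>= 2 levels).
#' @return List: `statistic` (H), `df`, `p_value`, `epsilon_sq`, `n`.
#' @export
kruskal_wallis_epsilon <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  n <- length(values)
  if (length(unique(values)) == 1L) {
    ## fully tied data: no rank variance to explain
    return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1,
                epsilon_sq = 0, n = n))
  }
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  list(statistic = H, df = unname(kt$parameter), p_value = kt$p.value,
       epsilon_sq = H / (n - 1), n = n)
}

#' Dunn's post-hoc test with Benjamini-Hochberg correction
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups; two-sided p-values adjusted by
#' BH across all pairs.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 3 levels for a meaningful post-hoc).
#' @return Data frame: `group1`, `group2`, `z`, `p`, `q` (BH-adjusted).
#' @export
dunn_posthoc_fdr <- function(values, groups) {
  groups <- factor(groups)
  g <- levels(groups)
  if (length(g) < 2L) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  ties <- table(values)
  T_ <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - T_ / (12 * (N - 1))
  pairs <- utils::combn(seq_along(g), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    z <- (rbar[[i]] - rbar[[j]]) /
      sqrt(var_base * (1 / ns[i] + 1 / ns[j]))
    data.frame(group1 = g[i], group2 = g[j], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Paired and unpaired rank / location tests
#'
#' Thin dispatcher over the standard tests used to compare model
#' performance vectors: Mann-Whitney U (unpaired ranks), Wilcoxon
#' signed-rank (paired), and the one-sample t-test.  All-zero paired
#' differences are degenerate for the signed-rank test and are reported as
#' `p = 1` with statistic 0.
#'
#' @param a,b Numeric vectors (`b` is the null mean for `one_sample_t`,
#'   default 0; required for the other kinds).
#' @param kind One of `"mann_whitney"`, `"wilcoxon_signed_rank"`,
#'   `"one_sample_t"`.
#' @param alternative Passed to the underlying test (default two-sided).
#' @return List: `statistic`, `p_value`, `kind`, `alternative`.
#' @export
paired_test <- function(a, b = NULL,
                        kind = c("mann_whitney", "wilcoxon_signed_rank",
                                 "one_sample_t"),
                        alternative = "two.sided") {
  kind <- match.arg(kind)
  res <- switch(kind,
    mann_whitney = {
      ht <- stats::wilcox.test(a, b, alternative = alternative,
                               exact = FALSE, correct = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    wilcoxon_signed_rank = {
      if (length(a) != length(b)) stop("paired vectors must match in length")
      d <- a - b
      if (all(d == 0)) {
        list(statistic = 0, p_value = 1)
      } else {
        ht <- stats::wilcox.test(a, b, paired = TRUE,
                                 alternative = alternative,
                                 exact = FALSE, correct = FALSE)
        list(statistic = unname(ht$statistic), p_value = ht$p.value)
      }
    },
    one_sample_t = {
      mu <- if (is.null(b)) 0 else b
      ht <- stats::t.test(a, mu = mu, alternative = alternative)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  c(res, list(kind = kind, alternative = alternative))
}
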