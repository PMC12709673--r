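#' Call binders for one target from panning data
#'
#' A variant is called binding when it is present (reads >= `min_reads`)
#' in the final selection round of *both* replicates for the target.  The
#' default `min_reads = 1` is a pure presence call; a higher threshold can
#' be used to filter sequencing noise.
#'
#' @param panning Panning table (see [simulate_panning()] /
#'   [read_panning_tsv()]).
#' @param target Target name.
#' @param min_reads Minimum reads per replicate (default 1).
#' @param round Selection round used for the call (default 3).
#' @param replicates Replicates that must all contain the variant
#'   (default 1 and 2).
#' @return Character vector of binding variants (6-mers, sorted).
#' @export
call_binders <- function(panning, target, min_reads = 1L, round = 3L,
                         replicates = c(1L, 2L)) {
  sub <- panning[panning$target == target & panning$round == round, ]
  reps <- replicates
  sets <- lapply(reps, function(r) {
    rows <- sub[sub$replicate == r, ]
    if (nrow(rows) == 0L) {
      stop("no round-", round, " data for target ", target,
           ", replicate ", r)
    }
    rows <- rows[rows$reads >= min_reads, ]
    paste0(rows$cdr3_alpha, rows$cdr3_beta)
  })
  sort(Reduce(intersect, sets))
}

#' Build per-variant binding profiles and k-binding strata
#'
#' Given the binder sets of all seven targets, every variant in the
#' evaluated universe gets its bound set S and its k-binding (k = |S|, the
#' number of targets bound).  Variants observed in the experiment but
#' binding nothing form the k = 0 stratum.
#'
#' @param binder_sets Named list of character vectors (one per target, all
#'   seven required) of binding variants.
#' @param universe Character vector of all variants under evaluation.
#' @return Data frame: `variant`, one logical column per target, `k`.
#' @export
profile_variants <- function(binder_sets, universe) {
  if (is.null(names(binder_sets)) || anyNA(names(binder_sets))) {
    stop("binder_sets must be a named list")
  }
  universe <- unique(universe)
  bound <- vapply(binder_sets, function(s) universe %in% s,
                  logical(length(universe)))
  if (length(universe) == 1L) bound <- matrix(bound, nrow = 1L,
                                              dimnames = list(NULL, names(binder_sets)))
  df <- data.frame(variant = universe, bound, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$k <- as.integer(rowSums(bound))
  df
}

#' Tally k-binding stratum sizes
#'
#' @param profiles Profile data frame from [profile_variants()] or
#'   [ground_truth_profiles()].
#' @param n_targets Number of targets in the universe (default 7).
#' @return Named integer vector `n_0` ... `n_<n_targets>`.
#' @export
stratum_counts <- function(profiles, n_targets = 7L) {
  counts <- tabulate(profiles$k + 1L, nbins = n_targets + 1L)
  names(counts) <- paste0("n_", 0:n_targets)
  counts
}

#' One-sided binomial test of excess cross-reactivity
#'
#' Tests whether more variants bind two or more targets than expected if
#' targets were bound independently.  Under the null each target t is bound
#' with its empirical marginal probability p_t; the null probability q of a
#' variant being cross-reactive (k >= 2) is computed exactly by enumerating
#' the 2^7 outcome lattice.  The observed number of k >= 2 variants among
#' the n-variant universe is then referred to the upper tail of
#' Binomial(n, q).
#'
#' @param profiles Profile data frame (variant x targets logical + `k`).
#' @return List with `q_null`, `observed`, `n`, `p_value`, and the
#'   per-target marginal rates.
#' @export
crossreactivity_test <- function(profiles) {
  target_cols <- setdiff(names(profiles), c("variant", "k"))
  n <- nrow(profiles)
  rates <- colMeans(profiles[, target_cols, drop = FALSE])
  if (any(rates < 0 | rates > 1)) stop("marginal rates outside [0, 1]")
  q <- prob_k_ge_2(rates)
  observed <- sum(profiles$k >= 2L)
  p <- stats::pbinom(observed - 1L, n, q, lower.tail = FALSE)
  list(q_null = q, observed = observed, n = n, p_value = p,
       marginal_rates = rates)
}

## Exact P(k >= 2) for independent Bernoulli(p_t) targets, by enumerating
## all 2^T binding patterns.
prob_k_ge_2 <- function(p) {
  T_ <- length(p)
  q <- 0
  for (m in 0:(2^T_ - 1L)) {
    bits <- as.integer(intToBits(m))[seq_len(T_)]
    if (sum(bits) >= 2L) {
      q <- q + prod(ifelse(bits == 1L, p, 1 - p))
    }
  }
  q
}
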