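## The seven 9-mer peptide targets presented by HLA-A*02:01.  These are
## fixed published sequences, used here to seed distinct per-target binding
## preferences in the simulator.
TARGET_PEPTIDES <- c(
  Tax  = "LLFGYPVYV",
  HUD  = "LGYGFVNYI",
  BENE = "LLQGWVMYV",
  F    = "TMGGYCGYL",
  TY   = "SLHGYKKYL",
  TM   = "TLWGWVKYV",
  HOM  = "NLQGSPVYV"
)

TARGET_NAMES <- names(TARGET_PEPTIDES)

## Simulator similarity table: BLOSUM50 rank-standardized within each
## preferred-residue column.  Raw BLOSUM columns differ widely in spread and
## tail shape (tryptophan's is extreme), which would make a position's
## effective importance depend on its consensus residue rather than on the
## position weight alone; replacing scores by their within-column ranks
## (then centering/scaling) gives every column the same score distribution
## while preserving the within-column order, so the consensus residue still
## maximizes each position's score and the position weights alone set the
## importance hierarchy.
similarity_from_blosum <- function(alphabet) {
  b <- blosum50_table()[alphabet$letters, alphabet$letters]
  sim <- apply(b, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (r - mean(r)) / stats::sd(r)
  })
  rownames(sim) <- rownames(b)
  sim
}

#' Construct a ground-truth binding landscape
#'
#' The simulator's binding rule is additive over the six CDR3 positions: the
#' affinity of a variant for a target is the position-weight-weighted sum of
#' similarity scores between the variant residue and the target's preferred
#' (consensus) residue at that position.  Similarity defaults to BLOSUM50,
#' so variants near a target's consensus in substitution space score
#' highest.  A variant binds a target when its affinity reaches the
#' per-target threshold.
#'
#' Cross-reactivity is built in structurally: every target shares the same
#' alpha-chain consensus (default `"DSW"`, the dominant alpha motif), and
#' the alpha positions carry most of the weight, so variants with a strong
#' alpha match tend to bind many targets at once while the beta positions
#' discriminate among them.  The default position weights are strictly
#' ordered `a99 > a101 > b98 > a100 > b100 > b99`, giving the generator a
#' known residue-importance hierarchy that downstream masked-training
#' analyses should recover.
#'
#' @param alphabet Library alphabet.
#' @param alpha_consensus 3-letter alpha-chain consensus shared by all
#'   targets.
#' @param beta_consensus Named character vector (length 7) of 3-letter
#'   beta-chain consensi; defaults are read off the variable anchor
#'   positions (P3, P5, P7) of the seven target peptides, so related
#'   peptides get related beta preferences.
#' @param position_weights Named nonnegative weights for the six positions.
#' @param binding_rate Target marginal binder fraction among uniformly
#'   random variants used to calibrate per-target thresholds.
#' @param noise_sd Standard deviation of the Gaussian affinity noise used by
#'   [true_binding()] draws (0 = deterministic rule).
#' @param calibration_n,calibration_seed Monte-Carlo sample used once, with
#'   a fixed internal seed, to place each threshold at the `1 -
#'   binding_rate` affinity quantile.
#' @return Object of class `kb_landscape`.
#' @export
make_landscape <- function(alphabet = make_alphabet(),
                           alpha_consensus = "DSW",
                           beta_consensus = NULL,
                           position_weights = c(a99 = 1.00, a100 = 0.37,
                                                a101 = 0.72, b98 = 0.52,
                                                b99 = 0.15, b100 = 0.26),
                           binding_rate = 0.03,
                           noise_sd = 1,
                           calibration_n = 40000L,
                           calibration_seed = 99L) {
  if (is.null(beta_consensus)) {
    beta_consensus <- vapply(TARGET_PEPTIDES, function(p) {
      paste0(substr(p, 3, 3), substr(p, 5, 5), substr(p, 7, 7))
    }, character(1))
  }
  stopifnot(length(beta_consensus) == 7L, !is.null(names(beta_consensus)))
  if (!setequal(names(position_weights), CDR3_POSITIONS)) {
    stop("position_weights must be named for all of: ",
         paste(CDR3_POSITIONS, collapse = ", "))
  }
  position_weights <- position_weights[CDR3_POSITIONS]
  if (any(position_weights < 0)) stop("position weights must be nonnegative")
  consensus <- paste0(alpha_consensus, beta_consensus)
  names(consensus) <- names(beta_consensus)
  check_variants(consensus, alphabet, length_ = 6L)

  sim <- similarity_from_blosum(alphabet)

  ls <- structure(list(
    targets = names(consensus),
    consensus = consensus,
    position_weights = position_weights,
    similarity = sim,
    thresholds = NULL,
    noise_sd = noise_sd,
    alphabet = alphabet
  ), class = "kb_landscape")

  ## Per-target threshold at the (1 - binding_rate) quantile of the affinity
  ## distribution over uniformly random library variants.
  vs <- sample_variants(calibration_n, alphabet, seed = calibration_seed)
  aff <- affinity_matrix(vs, ls)
  ls$thresholds <- vapply(seq_along(ls$targets), function(j) {
    as.numeric(stats::quantile(aff[, j], 1 - binding_rate, names = FALSE))
  }, numeric(1))
  names(ls$thresholds) <- ls$targets
  ls
}

#' @export
print.kb_landscape <- function(x, ...) {
  cat("Binding landscape over", length(x$targets), "targets:",
      paste(x$targets, collapse = ", "), "\n")
  cat("Position weights:",
      paste(sprintf("%s=%.2f", names(x$position_weights),
                    x$position_weights), collapse = ", "), "\n")
  cat("Noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Additive position-weighted affinity
#'
#' `affinity()` returns the affinity of each variant for one target;
#' `affinity_matrix()` returns the full variants x targets matrix.  The
#' score is `sum_p w_p * similarity(variant[p], consensus[target][p])` and
#' is deterministic.
#'
#' @param variants Character vector of 6-mers.
#' @param target Target name.
#' @param landscape A [make_landscape()] object.
#' @return Numeric vector (or matrix) of affinities.
#' @export
affinity <- function(variants, target, landscape) {
  if (!target %in% landscape$targets) stop("unknown target: ", target)
  affinity_matrix(variants, landscape)[, target]
}

#' @rdname affinity
#' @export
affinity_matrix <- function(variants, landscape) {
  ab <- landscape$alphabet
  idx <- variant_index_matrix(variants, ab)
  sim <- landscape$similarity[ab$letters, ab$letters]
  w <- landscape$position_weights
  out <- matrix(0, nrow = length(variants), ncol = length(landscape$targets),
                dimnames = list(NULL, landscape$targets))
  cons_idx <- variant_index_matrix(landscape$consensus, ab)
  for (j in seq_along(landscape$targets)) {
    a <- numeric(length(variants))
    for (p in seq_along(w)) {
      a <- a + w[[p]] * sim[cbind(idx[, p], cons_idx[j, p])]
    }
    out[, j] <- a
  }
  out
}

#' Draw noisy binding outcomes under the ground-truth rule
#'
#' A variant binds when `affinity + Normal(0, noise_sd) >= threshold`.
#' With `noise_sd = 0` the rule is deterministic and equals the ground
#' truth used by [ground_truth_profiles()].
#'
#' @inheritParams affinity
#' @param seed Integer seed for the noise draws.
#' @return Logical vector.
#' @export
true_binding <- function(variants, target, landscape, seed = 1L) {
  a <- affinity(variants, target, landscape)
  thr <- landscape$thresholds[[target]]
  if (landscape$noise_sd == 0) return(a >= thr)
  with_seed(seed, a + stats::rnorm(length(a), 0, landscape$noise_sd) >= thr)
}

#' Noise-free ground-truth binding profiles
#'
#' Evaluates the deterministic binding rule (noise_sd treated as 0) for
#' every variant against every target; this is the generator's ground truth
#' against which parameter-recovery analyses are scored.
#'
#' @param variants Character vector of 6-mers.
#' @param landscape A [make_landscape()] object.
#' @return Data frame: `variant`, one logical column per target, and `k`
#'   (number of targets bound).
#' @export
ground_truth_profiles <- function(variants, landscape) {
  aff <- affinity_matrix(variants, landscape)
  bound <- sweep(aff, 2L, landscape$thresholds, ">=")
  df <- data.frame(variant = variants, bound, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$k <- as.integer(rowSums(bound))
  df
}

#' Serialize / restore a landscape as YAML
#'
#' Stores targets, consensi, weights, thresholds and noise so a simulation
#' can be reproduced from its config alone (the similarity table is
#' reconstructed from the named scheme).
#'
#' @param landscape A [make_landscape()] object.
#' @param path File path.
#' @export
write_landscape_yaml <- function(landscape, path) {
  yaml::write_yaml(list(
    targets = as.list(landscape$consensus),
    position_weights = as.list(landscape$position_weights),
    thresholds = as.list(landscape$thresholds),
    noise_sd = landscape$noise_sd,
    similarity = "BLOSUM50",
    alphabet_excluded = landscape$alphabet$excluded
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_landscape_yaml
#' @export
read_landscape_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ab <- make_alphabet(y$alphabet_excluded)
  ls <- structure(list(
    targets = names(y$targets),
    consensus = unlist(y$targets),
    position_weights = unlist(y$position_weights)[CDR3_POSITIONS],
    similarity = similarity_from_blosum(ab),
    thresholds = unlist(y$thresholds),
    noise_sd = y$noise_sd,
    alphabet = ab
  ), class = "kb_landscape")
  ls
}
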