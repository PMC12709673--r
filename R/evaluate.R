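#' k-stratified cross-validation folds
#'
#' Assigns every variant to exactly one validation fold, stratifying by
#' k-binding so that rare high-k strata are spread as evenly as possible
#' across folds.
#'
#' @param k Integer vector of per-example k values.
#' @param n_folds Number of folds (default 10, i.e. 9:1 splits).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
make_folds <- function(k, n_folds = 10L, seed = 1L) {
  folds <- integer(length(k))
  with_seed(seed, {
    for (kk in unique(k)) {
      ix <- which(k == kk)
      ix <- ix[sample.int(length(ix))]
      folds[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  folds
}

## Core CV engine.  `trainer(xtr, ytr, ktr, seed)` must return an object
## whose predict(obj, x) yields a probability matrix.  `folds_run` selects
## a subset of folds to execute (the partition is still over all folds).
cv_engine <- function(x, y, k, trainer, scheme_name,
                      n_folds = 10L, seeds = c(1L, 2L), folds_run = NULL,
                      per_stratum = TRUE) {
  y <- as.matrix(y)
  targets <- colnames(y)
  if (is.null(targets)) targets <- paste0("t", seq_len(ncol(y)))
  if (is.null(folds_run)) folds_run <- seq_len(n_folds)
  out <- list()
  for (seed in seeds) {
    fold_id <- make_folds(k, n_folds, seed = seed)
    for (f in folds_run) {
      val <- fold_id == f
      model <- trainer(x[!val, , drop = FALSE], y[!val, , drop = FALSE],
                       k[!val], seed = seed * 10000L + f)
      prob <- stats::predict(model, x[val, , drop = FALSE])
      rows <- fold_metric_rows(y[val, , drop = FALSE], prob, k[val],
                               targets, per_stratum = per_stratum)
      rows$scheme <- scheme_name
      rows$seed <- seed
      rows$fold <- f
      out[[length(out) + 1L]] <- rows
    }
  }
  res <- do.call(rbind, out)
  res[, c("scheme", "seed", "fold", "stratum", "target", "f1", "auprc", "n")]
}

mlp_trainer <- function(config) {
  function(xtr, ytr, ktr, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed %% .Machine$integer.max)
    mlp_train(xtr, ytr, k = ktr, config = cfg)
  }
}

#' Cross-validated evaluation of the MLP classifier
#'
#' Embeds the variants under one scheme, trains the stratum-weighted MLP on
#' each training split and scores the held-out fold: F1 (threshold 0.5) and
#' average precision, overall (micro across all target cells), per target,
#' and per k-binding stratum.  Cells where a metric is undefined (e.g. no
#' positives in a stratum-fold) are recorded as `NA`, not zero.
#'
#' @param variants Character vector of CDR3 sequences (full or masked, all
#'   the same length).
#' @param labels 0/1 matrix, one column per target.
#' @param k Integer per-variant k-binding used for stratification and the
#'   sampler; defaults to `rowSums(labels)`.
#' @param scheme An [embedding_scheme()] (or scheme name).
#' @param config An [mlp_config()].
#' @param n_folds,seeds Fold count and seed replicates (defaults 10 and
#'   `c(1, 2)`).
#' @param folds_run Optional subset of folds to execute, for scaled-down
#'   runs; the fold partition itself is unchanged.
#' @param per_stratum Include per-stratum metric rows (default TRUE).
#' @return Tidy data frame: `scheme`, `seed`, `fold`, `stratum`, `target`,
#'   `f1`, `auprc`, `n`.
#' @export
cross_validate <- function(variants, labels, k = NULL,
                           scheme = embedding_scheme("BLOSUM50"),
                           config = mlp_config(), n_folds = 10L,
                           seeds = c(1L, 2L), folds_run = NULL,
                           per_stratum = TRUE) {
  if (is.character(scheme)) scheme <- embedding_scheme(scheme)
  if (is.null(k)) k <- as.integer(rowSums(labels))
  x <- embed_sequences(variants, scheme)
  cv_engine(x, labels, k, mlp_trainer(config), scheme$name,
            n_folds = n_folds, seeds = seeds, folds_run = folds_run,
            per_stratum = per_stratum)
}

## Per-target logistic regression on the embedded sequences.
logistic_fit <- function(xtr, ytr) {
  X <- cbind(1, xtr)
  coefs <- lapply(seq_len(ncol(ytr)), function(j) {
    yt <- ytr[, j]
    if (length(unique(yt)) < 2L) {
      ## degenerate single-class fold: constant predictor
      c(stats::qlogis(min(max(mean(yt), 1e-6), 1 - 1e-6)),
        rep(0, ncol(xtr)))
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(X, yt, family = stats::binomial()))
      b <- fit$coefficients
      b[!is.finite(b)] <- 0
      b
    }
  })
  structure(list(coefs = coefs), class = "kb_logistic")
}

#' @export
predict.kb_logistic <- function(object, x, ...) {
  X <- cbind(1, as.matrix(x))
  vapply(object$coefs, function(b) as.vector(stats::plogis(X %*% b)),
         numeric(nrow(X)))
}

#' Per-target logistic-regression baseline
#'
#' Seven independent binary logistic models (no shared weights, no
#' stratum-weighted sampling) evaluated on exactly the same fold partitions
#' and seeds as [cross_validate()], so MLP-vs-logistic comparisons are
#' paired cell by cell.
#'
#' @inheritParams cross_validate
#' @return Tidy metric data frame (scheme tagged `"<name>:logistic"`).
#' @export
logistic_baseline <- function(variants, labels, k = NULL,
                              scheme = embedding_scheme("BLOSUM50"),
                              n_folds = 10L, seeds = c(1L, 2L),
                              folds_run = NULL, per_stratum = TRUE) {
  if (is.character(scheme)) scheme <- embedding_scheme(scheme)
  if (is.null(k)) k <- as.integer(rowSums(labels))
  x <- embed_sequences(variants, scheme)
  trainer <- function(xtr, ytr, ktr, seed) logistic_fit(xtr, ytr)
  cv_engine(x, labels, k, trainer, paste0(scheme$name, ":logistic"),
            n_folds = n_folds, seeds = seeds, folds_run = folds_run,
            per_stratum = per_stratum)
}

#' Permuted-label MLP null baseline
#'
#' Within each training fold the rows of the label matrix are randomly
#' permuted across variants (a bijection: the label multiset is
#' preserved), breaking the sequence-label relationship while leaving the
#' validation fold intact; the MLP is then retrained and evaluated as
#' usual.  Validation metrics of this null model reflect what the
#' architecture can achieve with no usable sequence signal.
#'
#' @inheritParams cross_validate
#' @return Tidy metric data frame (scheme tagged `"<name>:permuted"`).
#' @export
permutation_baseline <- function(variants, labels, k = NULL,
                                 scheme = embedding_scheme("BLOSUM50"),
                                 config = mlp_config(), n_folds = 10L,
                                 seeds = c(1L, 2L), folds_run = NULL,
                                 per_stratum = TRUE) {
  if (is.character(scheme)) scheme <- embedding_scheme(scheme)
  if (is.null(k)) k <- as.integer(rowSums(labels))
  x <- embed_sequences(variants, scheme)
  trainer <- function(xtr, ytr, ktr, seed) {
    perm <- with_seed(seed + 777L, sample.int(nrow(ytr)))
    yp <- ytr[perm, , drop = FALSE]
    cfg <- config
    cfg$seed <- as.integer(seed %% .Machine$integer.max)
    mlp_train(xtr, yp, k = as.integer(rowSums(yp)), config = cfg)
  }
  cv_engine(x, labels, k, trainer, paste0(scheme$name, ":permuted"),
            n_folds = n_folds, seeds = seeds, folds_run = folds_run,
            per_stratum = per_stratum)
}

#' Write evaluation results as tidy TSV
#'
#' @param metrics Data frame from [cross_validate()] and friends.
#' @param path File path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
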