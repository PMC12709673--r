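#' The eight canonical mask configurations
#'
#' Six single-residue masks (one per CDR3 position) plus the two
#' whole-chain masks.
#'
#' @return Named list mapping mask label to the deleted position indices
#'   (1-6 in a99, a100, a101, b98, b99, b100 order).
#' @export
mask_specs <- function() {
  specs <- c(as.list(seq_len(6L)), list(1:3, 4:6))
  names(specs) <- c(CDR3_POSITIONS, "alpha", "beta")
  specs
}

#' Delete masked positions from variant sequences
#'
#' Masked datasets keep every row: after deletion, formerly distinct
#' variants may collapse onto the same shortened sequence while carrying
#' different label sets, and all such rows are retained (the model must
#' cope with the resulting label ambiguity).  No indicator of which
#' positions were removed is appended.
#'
#' @param variants Character vector of 6-mers.
#' @param mask Mask label (see [mask_specs()]).
#' @return Character vector of shortened sequences, same length as
#'   `variants`.
#' @export
mask_sequences <- function(variants, mask) {
  specs <- mask_specs()
  if (!mask %in% names(specs)) {
    stop("unknown mask label: ", mask, " (expected one of ",
         paste(names(specs), collapse = ", "), ")")
  }
  drop <- specs[[mask]]
  keep <- setdiff(1:6, drop)
  if (length(keep) == 0L) stop("cannot mask all six positions")
  vapply(strsplit(variants, ""), function(ch) paste(ch[keep], collapse = ""),
         character(1))
}

#' Residue importance by masked retraining
#'
#' Retrains and re-evaluates the classifier on each of the eight masked
#' datasets using the same fold partitions, seeds and hyperparameters as
#' the full-sequence run, then measures per-cell metric changes
#' `delta = masked - full` (negative = deterioration).  Residues are
#' ranked by mean delta-F1 over all per-target validation cells: the most
#' negative mask is the most important position.
#'
#' @inheritParams cross_validate
#' @param masks Mask labels to scan (default all eight).
#' @return List of class `kb_importance`:
#'   \describe{
#'     \item{deltas}{tidy data frame `mask`, `seed`, `fold`, `stratum`,
#'       `target`, `delta_f1`, `delta_auprc`;}
#'     \item{summary}{per-mask mean deltas;}
#'     \item{ranking}{the six residue labels ordered most- to
#'       least-important (ties broken lexicographically);}
#'     \item{full, masked}{the underlying metric tables.}
#'   }
#' @export
masked_importance <- function(variants, labels, k = NULL,
                              scheme = embedding_scheme("BLOSUM50"),
                              config = mlp_config(), n_folds = 10L,
                              seeds = c(1L, 2L), folds_run = NULL,
                              masks = names(mask_specs())) {
  if (is.character(scheme)) scheme <- embedding_scheme(scheme)
  if (is.null(k)) k <- as.integer(rowSums(labels))
  full <- cross_validate(variants, labels, k, scheme, config,
                         n_folds = n_folds, seeds = seeds,
                         folds_run = folds_run)
  masked <- list()
  deltas <- list()
  key_cols <- c("seed", "fold", "stratum", "target")
  for (m in masks) {
    mv <- mask_sequences(variants, m)
    res <- cross_validate(mv, labels, k, scheme, config,
                          n_folds = n_folds, seeds = seeds,
                          folds_run = folds_run)
    merged <- merge(full, res, by = key_cols, suffixes = c("_full", "_masked"))
    d <- data.frame(mask = m, merged[key_cols],
                    delta_f1 = merged$f1_masked - merged$f1_full,
                    delta_auprc = merged$auprc_masked - merged$auprc_full,
                    stringsAsFactors = FALSE)
    masked[[m]] <- res
    deltas[[m]] <- d
  }
  deltas <- do.call(rbind, deltas)
  rownames(deltas) <- NULL

  ## aggregate over the per-target cells of the unrestricted stratum
  cell <- deltas[deltas$stratum == "all" & deltas$target != "all", ]
  summary <- do.call(rbind, lapply(split(cell, cell$mask), function(d) {
    data.frame(mask = d$mask[1],
               mean_delta_f1 = mean(d$delta_f1, na.rm = TRUE),
               mean_delta_auprc = mean(d$delta_auprc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  residue_masks <- intersect(CDR3_POSITIONS, summary$mask)
  rs <- summary[summary$mask %in% residue_masks, ]
  ranking <- rs$mask[order(rs$mean_delta_f1, rs$mask)]

  structure(list(deltas = deltas, summary = summary, ranking = ranking,
                 full = full, masked = masked),
            class = "kb_importance")
}

#' @export
print.kb_importance <- function(x, ...) {
  cat("Residue importance ranking (most important first):\n ",
      paste(x$ranking, collapse = " > "), "\n")
  print(x$summary)
  invisible(x)
}

#' Alpha- versus beta-chain masking comparison
#'
#' Paired Wilcoxon signed-rank test of the per-cell metric deterioration
#' under the alpha-chain mask against the beta-chain mask.  The default
#' alternative `"less"` tests the directional hypothesis that masking the
#' alpha chain deteriorates performance more (more negative deltas).
#'
#' @param importance A [masked_importance()] result containing both chain
#'   masks.
#' @param metric `"delta_f1"` or `"delta_auprc"`.
#' @param alternative Test sidedness (default `"less"`).
#' @return A [paired_test()] result.
#' @export
chain_comparison <- function(importance, metric = "delta_f1",
                             alternative = "less") {
  d <- importance$deltas
  cell <- d[d$stratum == "all" & d$target != "all", ]
  a <- cell[cell$mask == "alpha", ]
  b <- cell[cell$mask == "beta", ]
  key <- c("seed", "fold", "target")
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  ok <- stats::complete.cases(m[, paste0(metric, c("_a", "_b"))])
  paired_test(m[[paste0(metric, "_a")]][ok], m[[paste0(metric, "_b")]][ok],
              kind = "wilcoxon_signed_rank", alternative = alternative)
}

#' Read an interface-energy table
#'
#' Tab-separated `mask` / `delta_isc` table of median interface-score
#' changes after computational alanine substitution (externally computed;
#' lower interface score = more stable, so a positive `delta_isc` means
#' the substitution destabilized the interface).
#'
#' @param path TSV path with columns `mask` and `delta_isc`.
#' @return Data frame.
#' @export
read_energy_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mask", "delta_isc") %in% names(df))) {
    stop("energy table must have columns `mask` and `delta_isc`")
  }
  df
}

#' Correlate masking importance with interface-energy changes
#'
#' Spearman rank correlation between per-mask mean metric deterioration
#' and the externally computed interface-score change, over the mask
#' labels present in both tables.
#'
#' @param importance A [masked_importance()] result.
#' @param energies Data frame from [read_energy_tsv()].
#' @param metric `"mean_delta_f1"` or `"mean_delta_auprc"`.
#' @return List: `rho`, `p_value`, `n`, and the merged table.
#' @export
correlate_energy <- function(importance, energies,
                             metric = "mean_delta_f1") {
  m <- merge(importance$summary, energies, by = "mask")
  if (nrow(m) < 3L) stop("need at least 3 shared mask labels, got ", nrow(m))
  if (length(unique(m$delta_isc)) == 1L ||
      length(unique(m[[metric]])) == 1L) {
    return(list(rho = 0, p_value = 1, n = nrow(m), table = m))
  }
  ct <- suppressWarnings(
    stats::cor.test(m[[metric]], m$delta_isc, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
       table = m)
}
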