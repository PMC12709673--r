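#' Simulation configuration for panning experiments
#'
#' @param n_variants Number of distinct library variants carried into the
#'   selection (sampled uniformly from the 19^6 space).  The default of
#'   2e5 is a desk-scale stand-in for the full ~4.7e7 library.
#' @param depth Sequencing reads drawn per (target, replicate, round).
#' @param n_rounds Number of selection rounds after the round-0 input
#'   library (default 3).
#' @param enrichment_sharpness Exponential rate applied to
#'   `affinity - threshold` when amplifying a variant between rounds.  The
#'   default of 3 models stringent bead selection: after three rounds a
#'   variant just one affinity unit below threshold is depleted ~8000-fold
#'   relative to a threshold-level one, so round-3 presence tracks true
#'   binding even when sequencing depth exceeds library size.
#' @param leak Lower clip on the per-round enrichment factor, modelling
#'   nonspecific carryover of non-binders.
#' @param n_replicates Independent selection replicates per target.
#' @param seed Master seed; per-(target, replicate) child streams are
#'   derived from it deterministically.
#' @return List of class `kb_simconfig`.
#' @export
sim_config <- function(n_variants = 2e5, depth = 1e6, n_rounds = 3L,
                       enrichment_sharpness = 3, leak = 1e-4,
                       n_replicates = 2L, seed = 1L) {
  stopifnot(n_variants >= 1, depth >= 1, n_rounds >= 1, leak > 0,
            enrichment_sharpness >= 0)
  structure(list(n_variants = as.integer(n_variants), depth = as.integer(depth),
                 n_rounds = as.integer(n_rounds),
                 enrichment_sharpness = enrichment_sharpness, leak = leak,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "kb_simconfig")
}

#' Simulate multi-round magnetic-bead panning with sequencing readout
#'
#' Emulates iterative display selection of a randomized CDR3 library
#' against each target: the round-0 input library is uniform over the
#' sampled variants; each selection round multiplies a variant's abundance
#' by `max(exp(sharpness * (affinity - threshold)), leak)`, renormalizes,
#' and draws `depth` sequencing reads multinomially.  As abundance
#' concentrates on strong binders, weak variants fall below the sequencing
#' floor and drop out of the observed reads, reproducing the decay of
#' unique-sequence counts and the growth of top-clone read share over
#' rounds.  Replicates run the same landscape under independent read-noise
#' streams.
#'
#' @param landscape A [make_landscape()] object.
#' @param config A [sim_config()] object.
#' @param variants Optional explicit variant pool; defaults to
#'   `sample_variants(config$n_variants, seed = config$seed)`.
#' @return A panning table: data frame with columns `target`, `replicate`,
#'   `round`, `cdr3_alpha`, `cdr3_beta`, `reads` (only rows with
#'   `reads > 0`).  The config is attached as attribute `"config"`.
#' @export
simulate_panning <- function(landscape, config = sim_config(),
                             variants = NULL) {
  if (is.null(variants)) {
    variants <- sample_variants(config$n_variants, landscape$alphabet,
                                seed = config$seed)
  }
  n <- length(variants)
  aff <- affinity_matrix(variants, landscape)
  chains <- split_chains(variants)

  ## deterministic child seeds per (target, replicate)
  n_streams <- length(landscape$targets) * config$n_replicates
  child_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, n_streams))
  out <- vector("list", n_streams * (config$n_rounds + 1L))
  slot <- 1L
  stream <- 0L
  for (t in seq_along(landscape$targets)) {
    tname <- landscape$targets[[t]]
    fac <- pmax(exp(config$enrichment_sharpness *
                      (aff[, t] - landscape$thresholds[[t]])), config$leak)
    for (rep_ in seq_len(config$n_replicates)) {
      stream <- stream + 1L
      rounds <- with_seed(child_seeds[[stream]], {
        ab <- rep(1 / n, n)
        acc <- list(`0` = as.vector(stats::rmultinom(1L, config$depth, ab)))
        for (r in seq_len(config$n_rounds)) {
          ab <- ab * fac
          ab <- ab / sum(ab)
          acc[[as.character(r)]] <-
            as.vector(stats::rmultinom(1L, config$depth, ab))
        }
        acc
      })
      for (r in names(rounds)) {
        keep <- rounds[[r]] > 0L
        out[[slot]] <- data.frame(
          target = tname, replicate = rep_, round = as.integer(r),
          cdr3_alpha = chains$cdr3_alpha[keep],
          cdr3_beta = chains$cdr3_beta[keep],
          reads = rounds[[r]][keep], stringsAsFactors = FALSE)
        slot <- slot + 1L
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  res
}

#' Read / write panning tables as TSV
#'
#' The on-disk schema is
#' `target  replicate  round  cdr3_alpha  cdr3_beta  reads`.
#' `read_panning_tsv` validates the header, rejects malformed or
#' negative-read rows with the offending line number, and warns about
#' target names outside the standard seven (rows are kept).
#'
#' @param panning Panning data frame.
#' @param path File path.
#' @return The path (write) or the validated data frame (read).
#' @export
write_panning_tsv <- function(panning, path) {
  cols <- c("target", "replicate", "round", "cdr3_alpha", "cdr3_beta", "reads")
  stopifnot(all(cols %in% names(panning)))
  utils::write.table(panning[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panning_tsv
#' @export
read_panning_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("target", "replicate", "round", "cdr3_alpha", "cdr3_beta", "reads")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("panning TSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$reads) | df$reads < 0)
  if (length(bad)) {
    stop("negative or non-numeric reads at line ", bad[1] + 1L,
         " of ", path)
  }
  bad <- which(is.na(df$round) | is.na(df$replicate))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  }
  unknown <- setdiff(unique(df$target), TARGET_NAMES)
  if (length(unknown)) {
    warning("unknown target name(s): ", paste(unknown, collapse = ", "))
  }
  df[, cols]
}

#' Export variants as FASTA
#'
#' Sequence ID is the concatenated alpha+beta 6-mer.
#'
#' @param variants Character vector of 6-mers.
#' @param path Output file.
#' @export
write_variants_fasta <- function(variants, path) {
  x <- Biostrings::AAStringSet(variants)
  names(x) <- variants
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
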