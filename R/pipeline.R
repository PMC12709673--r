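#' Run the full analysis pipeline end to end
#'
#' Orchestrates simulate -> binder calling -> k-binding profiling -> logo
#' grid -> panning diagnostics -> cross-validated training on the three
#' embeddings -> logistic and permutation baselines -> residue mask scan
#' -> optional interface-energy correlation, writing every stage's output
#' as tidy TSV into `out_dir` together with a YAML manifest recording the
#' configuration, seeds, package version and per-file checksums.  Stages
#' can be run selectively; later stages require the outputs of earlier
#' ones within the same call.
#'
#' @param out_dir Output directory (created if missing).
#' @param landscape A [make_landscape()] (default landscape if NULL).
#' @param config A [sim_config()] describing the simulation scale.
#' @param model_config An [mlp_config()] for all trained models.
#' @param stages Character vector choosing stages; default runs all.
#' @param schemes Embedding names for the evaluation stage.
#' @param n_folds,seeds,folds_run Cross-validation layout.
#' @param energy_path Optional TSV of interface-energy changes for the
#'   correlation stage.
#' @param min_reads Binder-call read threshold (default 1 = presence).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(out_dir,
                         landscape = NULL,
                         config = sim_config(n_variants = 5e3, depth = 5e4),
                         model_config = mlp_config(),
                         stages = c("simulate", "call_binding", "profile",
                                    "logos", "diagnostics", "evaluate",
                                    "baselines", "mask_scan", "energy"),
                         schemes = c("BLOSUM50", "VHSE8", "ONEHOT"),
                         n_folds = 10L, seeds = c(1L, 2L), folds_run = NULL,
                         energy_path = NULL, min_reads = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(landscape)) landscape <- make_landscape()
  res <- list()
  path <- function(f) file.path(out_dir, f)
  stage <- function(name) name %in% stages

  if (stage("simulate")) {
    res$panning <- simulate_panning(landscape, config)
    write_panning_tsv(res$panning, path("panning.tsv"))
    write_landscape_yaml(landscape, path("landscape.yaml"))
  }
  if (stage("call_binding")) {
    stopifnot(!is.null(res$panning))
    res$binders <- lapply(stats::setNames(landscape$targets,
                                          landscape$targets),
                          function(t) call_binders(res$panning, t,
                                                   min_reads = min_reads,
                                                   round = config$n_rounds))
  }
  if (stage("profile")) {
    stopifnot(!is.null(res$binders))
    p0 <- res$panning[res$panning$round == 0L, ]
    universe <- unique(paste0(p0$cdr3_alpha, p0$cdr3_beta))
    res$profiles <- profile_variants(res$binders, universe)
    res$strata <- stratum_counts(res$profiles)
    res$crossreactivity <- crossreactivity_test(res$profiles)
    prof_out <- cbind(split_chains(res$profiles$variant),
                      res$profiles[, setdiff(names(res$profiles), "variant")])
    utils::write.table(prof_out, path("profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (stage("logos")) {
    stopifnot(!is.null(res$profiles))
    res$logos <- logo_grid(res$profiles, alphabet = landscape$alphabet)
    for (nm in names(res$logos)) {
      write_logo_tsv(res$logos[[nm]],
                     path(paste0("logo_", gsub("[^A-Za-z0-9+]", "_", nm),
                                 ".tsv")))
    }
  }
  if (stage("diagnostics")) {
    stopifnot(!is.null(res$panning))
    res$diagnostics <- panning_diagnostics(res$panning)
    utils::write.table(res$diagnostics, path("diagnostics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  dataset <- NULL
  if (any(c("evaluate", "baselines", "mask_scan") %in% stages)) {
    stopifnot(!is.null(res$profiles))
    dataset <- list(
      variants = res$profiles$variant,
      labels = as.matrix(res$profiles[, landscape$targets, drop = FALSE]) * 1L,
      k = res$profiles$k)
  }
  if (stage("evaluate")) {
    res$metrics <- do.call(rbind, lapply(schemes, function(s) {
      cross_validate(dataset$variants, dataset$labels, dataset$k,
                     scheme = s, config = model_config, n_folds = n_folds,
                     seeds = seeds, folds_run = folds_run)
    }))
    write_metrics_tsv(res$metrics, path("metrics.tsv"))
  }
  if (stage("baselines")) {
    res$baselines <- rbind(
      logistic_baseline(dataset$variants, dataset$labels, dataset$k,
                        n_folds = n_folds, seeds = seeds,
                        folds_run = folds_run),
      permutation_baseline(dataset$variants, dataset$labels, dataset$k,
                           config = model_config, n_folds = n_folds,
                           seeds = seeds, folds_run = folds_run))
    write_metrics_tsv(res$baselines, path("baselines.tsv"))
  }
  if (stage("mask_scan")) {
    res$importance <- masked_importance(dataset$variants, dataset$labels,
                                        dataset$k, config = model_config,
                                        n_folds = n_folds, seeds = seeds,
                                        folds_run = folds_run)
    write_metrics_tsv(res$importance$deltas, path("importance_deltas.tsv"))
    utils::write.table(res$importance$summary, path("importance_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage("energy") && !is.null(energy_path) && !is.null(res$importance)) {
    res$energy <- correlate_energy(res$importance, read_energy_tsv(energy_path))
    utils::write.table(res$energy$table, path("energy_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   path("manifest.yaml"))
  manifest <- list(
    package = "kbindr",
    version = as.character(utils::packageVersion("kbindr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages,
    sim_config = unclass(config),
    model_config = unclass(model_config),
    checksums = as.list(tools::md5sum(files))
  )
  yaml::write_yaml(manifest, path("manifest.yaml"))
  res$manifest <- path("manifest.yaml")
  invisible(res)
}
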