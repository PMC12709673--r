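#' Position frequency matrix and information content for a variant set
#'
#' Computes, for each CDR3 position, the residue frequency distribution and
#' the information content in bits, `IC_p = log2(basis) - H_p`, where `H_p`
#' is the Shannon entropy of the position (the convention used by standard
#' protein logo tools).  The basis defaults to 20 (the full amino-acid
#' alphabet) even though the library uses 19 letters; set `basis = 19` to
#' normalize to the library alphabet instead.
#'
#' @param variants Nonempty character vector of equal-length sequences.
#' @param basis Alphabet size used for the entropy ceiling (default 20).
#' @param alphabet Library alphabet (rows of the frequency matrix).
#' @return Object of class `kb_logo`: list with `freq` (positions x
#'   letters), `ic` (bits per position) and `n` (number of sequences).
#' @export
build_logo <- function(variants, basis = 20L, alphabet = make_alphabet()) {
  if (length(variants) == 0L) stop("cannot build a logo from zero sequences")
  idx <- variant_index_matrix(variants, alphabet)
  L <- ncol(idx)
  freq <- t(apply(idx, 2L, function(col) {
    tabulate(col, nbins = alphabet$size) / length(col)
  }))
  colnames(freq) <- alphabet$letters
  rownames(freq) <- if (L == 6L) CDR3_POSITIONS else paste0("pos", seq_len(L))
  H <- apply(freq, 1L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(freq = freq, ic = log2(basis) - H, n = length(variants),
                 basis = basis),
            class = "kb_logo")
}

#' @export
print.kb_logo <- function(x, ...) {
  cat("Sequence logo over", x$n, "sequences; information content (bits):\n")
  print(round(x$ic, 3))
  invisible(x)
}

#' S-binding logo grid for k = 1 and k = 2 classes
#'
#' Builds one logo per nonempty S-binding class with |S| in {1, 2}: up to 7
#' target-specific (1-binding) logos plus up to 21 pairwise (2-binding)
#' logos, 28 classes in total for a 7-target universe.  Empty classes are
#' simply absent from the result.
#'
#' @param profiles Profile data frame (variant column, logical target
#'   columns, `k`).
#' @param basis,alphabet Passed to [build_logo()].
#' @return Named list of `kb_logo` objects; 1-binding classes are named by
#'   their target, 2-binding classes `"T1+T2"`.
#' @export
logo_grid <- function(profiles, basis = 20L, alphabet = make_alphabet()) {
  target_cols <- setdiff(names(profiles), c("variant", "k"))
  out <- list()
  for (t in target_cols) {
    v <- profiles$variant[profiles$k == 1L & profiles[[t]]]
    if (length(v)) out[[t]] <- build_logo(v, basis, alphabet)
  }
  pairs <- utils::combn(target_cols, 2L)
  for (j in seq_len(ncol(pairs))) {
    t1 <- pairs[1L, j]; t2 <- pairs[2L, j]
    v <- profiles$variant[profiles$k == 2L & profiles[[t1]] & profiles[[t2]]]
    if (length(v)) out[[paste(t1, t2, sep = "+")]] <-
        build_logo(v, basis, alphabet)
  }
  out
}

#' Write a logo frequency matrix as TSV
#'
#' Positions x residues, consumable by standard logo plotters.
#'
#' @param logo A `kb_logo` object.
#' @param path File path.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = rownames(logo$freq), logo$freq,
                   ic_bits = logo$ic, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Panning-progression diagnostics
#'
#' For every (target, replicate, round) cell: the number of unique variants
#' observed and the share of reads contributed by the 100 most-read
#' variants (ties at rank 100 broken by lexicographic variant order, so the
#' output is deterministic).  Healthy selections show unique counts
#' decreasing and top-100 share increasing over rounds.
#'
#' @param panning Panning table.
#' @param top_n Number of top variants (default 100).
#' @return Data frame: `target`, `replicate`, `round`, `n_unique`,
#'   `top_share`.
#' @export
panning_diagnostics <- function(panning, top_n = 100L) {
  key <- interaction(panning$target, panning$replicate, panning$round,
                     drop = TRUE)
  parts <- split(seq_len(nrow(panning)), key)
  rows <- lapply(parts, function(ix) {
    sub <- panning[ix, ]
    v <- paste0(sub$cdr3_alpha, sub$cdr3_beta)
    ord <- order(-sub$reads, v)
    total <- sum(sub$reads)
    top <- sum(sub$reads[ord][seq_len(min(top_n, length(ord)))])
    data.frame(target = sub$target[1], replicate = sub$replicate[1],
               round = sub$round[1], n_unique = length(unique(v)),
               top_share = top / total, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$target, res$replicate, res$round), ]
  rownames(res) <- NULL
  res
}
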