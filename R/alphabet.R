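#' @keywords internal
"_PACKAGE"

## Canonical amino-acid order used for all embedding tables and logo rows.
AA_CANONICAL <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

## CDR3 position labels: three randomized alpha-chain residues followed by
## three beta-chain residues.
CDR3_POSITIONS <- c("a99", "a100", "a101", "b98", "b99", "b100")

#' Construct the randomized CDR3 library alphabet
#'
#' The randomized library spans 19 of the 20 canonical amino acids at each of
#' the six CDR3 positions (library diversity 19^6, about 47 million
#' variants).  One residue is excluded from the degenerate codon design; by
#' default cysteine is omitted, the usual choice in display libraries to
#' avoid spurious disulfide formation.
#'
#' @param exclude Single one-letter code of the canonical amino acid left out
#'   of the library (default `"C"`).
#' @return An object of class `kb_alphabet`: a list with `letters` (ordered
#'   character vector, canonical order) and `size`.
#' @examples
#' ab <- make_alphabet()
#' ab$size            # 19
#' library_diversity(ab)
#' @export
make_alphabet <- function(exclude = "C") {
  if (!is.character(exclude) || length(exclude) != 1L ||
      !(exclude %in% AA_CANONICAL)) {
    stop("`exclude` must be one of the 20 canonical amino-acid letters, got ",
         deparse(exclude))
  }
  letters <- setdiff(AA_CANONICAL, exclude)
  structure(list(letters = letters, size = length(letters),
                 excluded = exclude),
            class = "kb_alphabet")
}

#' @export
print.kb_alphabet <- function(x, ...) {
  cat("CDR3 library alphabet:", x$size, "letters (",
      paste(x$letters, collapse = ""), "), excluded:", x$excluded, "\n")
  invisible(x)
}

#' Theoretical diversity of the randomized library
#'
#' Number of distinct six-residue CDR3 variants: `size^6`.
#'
#' @param alphabet A [make_alphabet()] object.
#' @param n_positions Number of randomized positions (default 6).
#' @return Numeric count (19^6 = 47,045,881 for the default alphabet).
#' @export
library_diversity <- function(alphabet = make_alphabet(), n_positions = 6L) {
  alphabet$size^n_positions
}

#' Assemble and validate CDR3 variant sequences
#'
#' Variants are represented as plain 6-character strings, alpha triplet
#' (a99, a100, a101) followed by beta triplet (b98, b99, b100).
#'
#' @param alpha,beta Character vectors of 3-residue chain sequences.
#' @param alphabet Library alphabet the residues must come from.
#' @return Character vector of 6-mers.
#' @export
tcr_variant <- function(alpha, beta, alphabet = make_alphabet()) {
  if (any(nchar(alpha) != 3L) || any(nchar(beta) != 3L)) {
    stop("alpha and beta chains must each be 3 residues long")
  }
  v <- paste0(alpha, beta)
  check_variants(v, alphabet)
  v
}

## Internal: validate that sequences only use alphabet letters and share a
## common length (6 for full variants, shorter after masking).
check_variants <- function(variants, alphabet, length_ = NULL) {
  if (length(variants) == 0L) stop("no variants supplied")
  n <- unique(nchar(variants))
  if (length(n) != 1L) stop("variants have mixed lengths: ",
                            paste(n, collapse = ", "))
  if (!is.null(length_) && n != length_) {
    stop("variants must be ", length_, "-mers, got ", n, "-mers")
  }
  bad <- setdiff(unique(strsplit(paste(variants, collapse = ""), "")[[1]]),
                 alphabet$letters)
  if (length(bad)) {
    stop("residues outside the library alphabet: ",
         paste(bad, collapse = ", "))
  }
  invisible(variants)
}

## Internal: n x L integer matrix of alphabet indices for equal-length
## sequences.  Stops on letters outside the alphabet.
variant_index_matrix <- function(variants, alphabet) {
  L <- unique(nchar(variants))
  if (length(L) != 1L) stop("variants have mixed lengths")
  chars <- strsplit(variants, "")
  idx <- matrix(match(unlist(chars), alphabet$letters),
                ncol = L, byrow = TRUE)
  if (anyNA(idx)) stop("variant residue not present in the alphabet")
  idx
}

#' Split 6-mer variants into chain components
#'
#' @param variants Character vector of 6-mers.
#' @return Data frame with columns `cdr3_alpha` and `cdr3_beta`.
#' @export
split_chains <- function(variants) {
  data.frame(cdr3_alpha = substr(variants, 1L, 3L),
             cdr3_beta  = substr(variants, 4L, 6L),
             stringsAsFactors = FALSE)
}

#' Uniformly sample distinct CDR3 variants from the library
#'
#' @param n Number of distinct variants requested.
#' @param alphabet Library alphabet.
#' @param seed Integer seed for reproducibility.
#' @return Character vector of `n` distinct 6-mers.
#' @export
sample_variants <- function(n, alphabet = make_alphabet(), seed = 1L) {
  if (n > library_diversity(alphabet)) {
    stop("requested more variants than the library contains")
  }
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      m <- ceiling((n - length(out)) * 1.05) + 10L
      chars <- sample(alphabet$letters, m * 6L, replace = TRUE)
      seqs <- apply(matrix(chars, ncol = 6L), 1L, paste, collapse = "")
      out <- unique(c(out, seqs))
    }
    out[seq_len(n)]
  })
}

## Internal: evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
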