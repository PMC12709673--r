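## VHSE descriptors (Mei et al. 2005, Biopolymers 80:775-786): eight
## principal-component scores per amino acid summarizing hydrophobic
## (VHSE1-2), steric (VHSE3-4) and electronic (VHSE5-8) properties.
VHSE8_TABLE <- matrix(c(
  #  VHSE1  VHSE2  VHSE3  VHSE4  VHSE5  VHSE6  VHSE7  VHSE8
    0.15, -1.11, -1.35, -0.92,  0.02, -0.91,  0.36, -0.48,  # A
   -1.47,  1.45,  1.24,  1.27,  1.55,  1.47,  1.30,  0.83,  # R
   -0.99,  0.00, -0.37,  0.69, -0.55,  0.85,  0.73, -0.80,  # N
   -1.15,  0.67, -0.41, -0.01, -2.68,  1.31,  0.03,  0.56,  # D
    0.18, -1.67, -0.46, -0.21,  0.00,  1.20, -1.61, -0.19,  # C
   -0.96,  0.12,  0.18,  0.16,  0.09,  0.42, -0.20, -0.41,  # Q
   -1.18,  0.40,  0.10,  0.36, -2.16, -0.17,  0.91,  0.02,  # E
   -0.20, -1.53, -2.63,  2.28, -0.53, -1.18,  2.01, -1.34,  # G
   -0.43, -0.25,  0.37,  0.19,  0.51,  1.28,  0.93,  0.65,  # H
    1.27, -0.14,  0.30, -1.80,  0.30, -1.61, -0.16, -0.13,  # I
    1.36,  0.07,  0.26, -0.80,  0.22, -1.37,  0.08, -0.62,  # L
   -1.17,  0.70,  0.70,  0.80,  1.64,  0.67,  1.63,  0.13,  # K
    1.01, -0.53,  0.43,  0.00,  0.23,  0.10, -0.86, -0.68,  # M
    1.52,  0.61,  0.96, -0.16,  0.25,  0.28, -1.33, -0.20,  # F
    0.22, -0.17, -0.50,  0.05, -0.01, -1.34, -0.19,  3.56,  # P
   -0.67, -0.86, -1.07, -0.41, -0.32,  0.27, -0.64,  0.11,  # S
   -0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79,  0.39,  # T
    1.50,  2.06,  1.79,  0.75,  0.75, -0.13, -1.01, -0.85,  # W
    0.61,  1.60,  1.17,  0.73,  0.53,  0.25, -0.96, -0.52,  # Y
    0.76, -0.92, -0.17, -1.91,  0.22, -1.40, -0.24, -0.03   # V
), nrow = 20L, byrow = TRUE,
   dimnames = list(AA_CANONICAL, paste0("VHSE", 1:8)))

## BLOSUM50 rows over the 20 canonical columns, in canonical order.
## Sourced from the Biostrings substitution-matrix data; raw integer scores
## are used without rescaling (any scaling is left to the model).
blosum50_table <- function() {
  env <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = env)
  env$BLOSUM50[AA_CANONICAL, AA_CANONICAL]
}

#' Define a per-residue sequence embedding scheme
#'
#' Three embeddings are supported for CDR3 sequences:
#' \describe{
#'   \item{BLOSUM50}{each residue maps to its 20-entry row of the BLOSUM50
#'     substitution matrix;}
#'   \item{VHSE8}{each residue maps to its eight published VHSE
#'     physicochemical principal-component scores;}
#'   \item{ONEHOT}{each residue maps to a 20-entry indicator vector.}
#' }
#' A length-L sequence embeds to a vector of `L * per_residue_dim` values,
#' so full 6-mers give 120 (BLOSUM50, one-hot) or 48 (VHSE8) dimensions.
#'
#' @param name One of `"BLOSUM50"`, `"VHSE8"`, `"ONEHOT"`.
#' @param alphabet Library alphabet the lookup must cover.
#' @return An object of class `kb_embedding` with elements `name`,
#'   `per_residue_dim` and `lookup` (matrix, rows = alphabet letters).
#' @examples
#' sc <- embedding_scheme("VHSE8")
#' sc$per_residue_dim  # 8
#' @export
embedding_scheme <- function(name = c("BLOSUM50", "VHSE8", "ONEHOT"),
                             alphabet = make_alphabet()) {
  name <- match.arg(name)
  lookup <- switch(name,
    BLOSUM50 = blosum50_table()[alphabet$letters, , drop = FALSE],
    VHSE8    = VHSE8_TABLE[alphabet$letters, , drop = FALSE],
    ONEHOT   = {
      m <- diag(20L)
      dimnames(m) <- list(AA_CANONICAL, AA_CANONICAL)
      m[alphabet$letters, , drop = FALSE]
    })
  structure(list(name = name, per_residue_dim = ncol(lookup),
                 lookup = lookup, alphabet = alphabet),
            class = "kb_embedding")
}

#' @export
print.kb_embedding <- function(x, ...) {
  cat("Embedding scheme", x$name, "-", x$per_residue_dim,
      "dimensions per residue\n")
  invisible(x)
}

#' Embed CDR3 sequences as a numeric matrix
#'
#' Residue vectors are concatenated in position order (alpha triplet then
#' beta triplet for full variants).  Masked sequences (shorter than six
#' residues after deleting one residue or a whole chain) embed the same
#' way over their remaining positions; no indicator of which positions were
#' removed is added, so the model only sees the shortened sequence.
#'
#' @param variants Character vector of equal-length sequences (1 to 6
#'   residues).
#' @param scheme An [embedding_scheme()] object.
#' @return Numeric matrix, one row per variant, `L * per_residue_dim`
#'   columns.
#' @export
embed_sequences <- function(variants, scheme) {
  stopifnot(inherits(scheme, "kb_embedding"))
  idx <- variant_index_matrix(variants, scheme$alphabet)
  L <- ncol(idx)
  if (L < 1L || L > 6L) stop("sequences must have 1-6 residues, got ", L)
  d <- scheme$per_residue_dim
  out <- matrix(0, nrow = nrow(idx), ncol = L * d)
  for (p in seq_len(L)) {
    out[, ((p - 1L) * d + 1L):(p * d)] <-
      scheme$lookup[idx[, p], , drop = FALSE]
  }
  colnames(out) <- paste(rep(seq_len(L), each = d),
                         rep(colnames(scheme$lookup), L), sep = ".")
  out
}

#' Export / import an embedding lookup table as TSV
#'
#' Rows are alphabet letters, columns are descriptor values; useful for
#' auditing the exact values a model was trained with.
#'
#' @param scheme An [embedding_scheme()] object.
#' @param path File path.
#' @return `write_embedding_tsv` returns `path` invisibly;
#'   `read_embedding_tsv` returns the lookup matrix.
#' @export
write_embedding_tsv <- function(scheme, path) {
  df <- data.frame(letter = rownames(scheme$lookup), scheme$lookup,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$letter
  m
}
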