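#' @keywords internal
"_PACKAGE"

#' @useDynLib slimclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median setNames sd cor
#' @importFrom utils combn data head write.table
NULL

# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
# All integer residue encodings in the package index into this vector.
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# BLOSUM62 marginal residue frequencies (Henikoff alignment blocks), the
# default null model for HMM scoring and the default residue distribution of
# the synthetic generator.
BLOSUM62_BACKGROUND <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

#' Background amino-acid frequencies
#'
#' Returns the null-model residue distribution used throughout the package:
#' either the BLOSUM62 marginal frequencies (default) or the uniform
#' distribution over the 20 canonical residues.
#'
#' @param kind `"blosum62"` (default) or `"uniform"`.
#' @return Named numeric vector of length 20 summing to 1, ordered
#'   alphabetically by one-letter code.
#' @export
aa_background <- function(kind = c("blosum62", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    return(setNames(rep(1 / 20, 20), AA))
  }
  BLOSUM62_BACKGROUND
}

#' Encode peptides as integer residue codes
#'
#' @param seqs Character vector of uppercase peptide strings.
#' @return List of integer vectors (1-based indices into the alphabet).
#' @keywords internal
aa_encode <- function(seqs) {
  lapply(strsplit(seqs, ""), function(ch) {
    idx <- match(ch, AA)
    if (anyNA(idx)) {
      stop("non-canonical residue in sequence: ",
           paste(ch[is.na(idx)], collapse = ","))
    }
    idx
  })
}

#' Default substitution matrix (BLOSUM62)
#'
#' Fetches BLOSUM62 from Biostrings and restricts/reorders it to the 20
#' canonical residues in alphabetical order.
#'
#' @return 20 x 20 symmetric integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA, AA]
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI/EMBOSS text format
#'
#' Parses the standard square scoring-matrix layout (comment lines starting
#' with `#`, a header row of residue codes, one labelled row per residue).
#' Rows/columns outside the 20-letter canonical alphabet (B, Z, X, `*`) are
#' dropped.
#'
#' @param path Path to the matrix file.
#' @return 20 x 20 numeric matrix ordered alphabetically by residue.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  missing <- setdiff(AA, intersect(labs, header))
  if (length(missing)) {
    stop("matrix is missing canonical residues: ", paste(missing, collapse = ","))
  }
  m <- vals[AA, AA]
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("substitution matrix is not symmetric")
  }
  if (any(diag(m) < apply(m, 1L, max))) {
    warning("matrix diagonal does not dominate all rows")
  }
  m
}
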