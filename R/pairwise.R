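# Inner-gap-free, shift-limited pairwise scoring used for greedy seeding.
# The only alignment freedom is a rigid offset of one peptide against the
# other; overhanging (trailing-gap) positions score 0, so the "limited number
# of trailing gaps" is enforced purely by the maximum shift.

#' Gapless shift-limited alignment score
#'
#' Scores two peptides under a substitution matrix over every rigid offset
#' `s` of `b` against `a` with `|s| <= max_shift` (residue `b[i]` pairs with
#' `a[i + s]`), and returns the best. No inner gaps are considered;
#' overhanging positions are unpenalized. Ties are broken toward smaller
#' `|s|`, then toward negative `s`.
#'
#' @param a,b Peptide strings (or 1-based integer residue codes).
#' @param matrix 20 x 20 substitution matrix, [blosum62()] by default.
#' @param max_shift Maximum absolute offset; must be smaller than both
#'   sequence lengths so the overlap is never empty.
#' @return List with `score`, `shift` (offset of `b` relative to `a`), and
#'   `overlap` (number of residue pairs scored).
#' @examples
#' gapless_shift_score("ACDE", "CDEA", max_shift = 2)
#' @export
gapless_shift_score <- function(a, b, matrix = blosum62(), max_shift = 1L) {
  ea <- if (is.character(a)) aa_encode(a)[[1L]] else as.integer(a)
  eb <- if (is.character(b)) aa_encode(b)[[1L]] else as.integer(b)
  if (length(ea) == 0L || length(eb) == 0L) stop("empty peptide")
  if (max_shift < 0L || max_shift >= min(length(ea), length(eb))) {
    stop("max_shift must be in [0, min(len(a), len(b)) - 1]")
  }
  cpp_shift_align(ea, eb, matrix, as.integer(max_shift))
}

#' Default absolute greedy-joining threshold
#'
#' The greedy threshold is expressed per residue and scaled by the median
#' sequence length: `round(theta * median(nchar(seqs)))`.
#'
#' @param seqs Character vector of peptides.
#' @param theta Per-residue threshold in substitution-matrix units.
#' @return Absolute score threshold.
#' @export
greedy_threshold <- function(seqs, theta = 2.0) {
  round(theta * stats::median(nchar(seqs)))
}
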