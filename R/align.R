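# Pairwise nucleotide alignment with the conventional scoring scheme:
# match +2, mismatch -3, gap of length L costs 5 + 2L (affine). Percent
# identity is computed over alignment columns, gaps counted in the
# denominator; an IUPAC-compatible pair (e.g. query A vs subject R) counts
# as a match, so degenerate reference bases never penalise a read. The
# dynamic programme itself is compiled (Gotoh algorithm); tests check it
# against independent full-matrix implementations.

#' Align two sequences and report percent identity
#'
#' Local (Smith-Waterman) alignment by default, with match +2, mismatch -3,
#' gap open -5, gap extend -2 (a gap of length L costs 5 + 2L). Identity is
#' `100 * matches / alignment_columns` with gap columns in the denominator;
#' IUPAC-compatible pairs count as matches. Traceback ties resolve
#' diagonal first, then gap-in-subject, then gap-in-query, so results are
#' deterministic.
#'
#' @param query,subject nucleotide strings (either may carry IUPAC codes).
#' @param type `"local"` (default) or `"global"`.
#' @return list with `percent_identity`, `alignment_length`, `score`, the
#'   aligned strings `aligned_query`, `aligned_subject`, and the 1-based
#'   `query_start`/`query_end`/`subject_start`/`subject_end` coordinates.
#' @export
align_identity <- function(query, subject, type = "local") {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  al <- .cpp_align_pair(toupper(query), toupper(subject), type == "local")
  al$percent_identity <-
    if (al$alignment_length > 0) 100 * al$matches / al$alignment_length else 0
  al
}
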