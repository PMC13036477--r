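IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set -> IUPAC code, keyed by sorted concatenation ("AG" -> "R", ...)
IUPAC_CODE_OF <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

#' Reverse complement of a nucleotide string
#'
#' IUPAC degeneracy codes are complemented symbol-wise (R <-> Y, etc.).
#'
#' @param x character vector of sequences (A/C/G/T/N plus IUPAC codes).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Bounded Levenshtein edit distance
#'
#' Banded dynamic programme: the result is exact whenever the true distance
#' is at most `cap`; any larger distance is reported as the sentinel
#' `cap + 1`. This is the distance used for dual-index demultiplexing.
#'
#' @param a,b character vectors of sequences (recycled to equal length).
#' @param cap non-negative integer band width / tolerance.
#' @return integer vector of distances, `cap + 1` meaning "greater than cap".
#' @examples
#' edit_distance("ACGT", "ACGT", cap = 2)   # 0
#' edit_distance("AAAA", "TTTT", cap = 2)   # 3 == cap + 1 sentinel
#' @export
edit_distance <- function(a, b, cap = 2L) {
  stopifnot(cap >= 0, all(nchar(a) > 0), all(nchar(b) > 0))
  .cpp_edit_distance(toupper(a), toupper(b), as.integer(cap))
}

#' Are two equal-length sequences IUPAC-compatible position by position?
#'
#' @param a,b character vectors of equal-length sequences.
#' @return logical vector; `TRUE` when every aligned symbol pair shares at
#'   least one concrete base.
#' @export
iupac_compatible <- function(a, b) {
  .cpp_iupac_compatible(toupper(a), toupper(b))
}

# locate `needle` inside `haystack` allowing edit errors; needle consumed
# fully, haystack window free. Returns list(dist, start, end) (1-based).
infix_search <- function(needles, haystack, iupac = FALSE) {
  .cpp_infix_search(toupper(needles), toupper(haystack), iupac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
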