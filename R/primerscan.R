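# Degenerate primer elongation from a curated multiple alignment:
# gap-column trimming (> 50% gaps removed), per-column conservation
# profiling, IUPAC consensus with a minor-allele frequency threshold, and
# exhaustive enumeration of seed-primer extensions to ~25-30 bases ranked
# by (fewest degeneracies, highest conservation, greatest length). The
# isothermal amplification chemistry is what pushes primers to this length.

# alignment = character matrix (rows = sequences, columns = positions) or
# seq_records of equal-length aligned sequences ('-' for gaps)
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    seqs <- if (is.data.frame(alignment)) alignment$seq else as.character(alignment)
    if (length(unique(nchar(seqs))) != 1)
      stop("ragged alignment: rows differ in length")
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  }
  m
}

#' Remove gap-rich alignment columns
#'
#' Columns with strictly more than `max_gap_fraction` gaps across all rows
#' are removed; row order is preserved. A column with exactly the threshold
#' fraction is retained.
#'
#' @param alignment character matrix or [seq_records] of aligned rows.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.5).
#' @return character matrix of the retained columns.
#' @export
trim_gappy_columns <- function(alignment, max_gap_fraction = 0.5) {
  m <- as_alignment_matrix(alignment)
  gapfrac <- colMeans(m == "-" | m == ".")
  m[, gapfrac <= max_gap_fraction, drop = FALSE]
}

#' Per-column base frequencies, gap fraction and conservation
#'
#' @param alignment character matrix or [seq_records] of aligned rows.
#' @return data.frame of class `alignment_profile`, one row per column:
#'   `A`, `C`, `G`, `T` (frequencies among non-gap rows), `gap_fraction`,
#'   `conservation` (max base frequency among non-gap rows).
#' @export
alignment_profile <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  prof <- t(apply(m, 2, function(col) {
    gaps <- col == "-" | col == "."
    ng <- col[!gaps]
    f <- if (length(ng)) table(factor(ng, levels = DNA_BASES)) / length(ng)
         else setNames(rep(0, 4), DNA_BASES)
    c(as.numeric(f), mean(gaps), if (length(ng)) max(f) else 0)
  }))
  out <- as.data.frame(prof)
  names(out) <- c(DNA_BASES, "gap_fraction", "conservation")
  class(out) <- c("alignment_profile", "data.frame")
  out
}

#' IUPAC consensus code for a column
#'
#' The code covers every base whose frequency (among non-gap rows) is at
#' least `minor_freq_threshold`; rare variants below the threshold are
#' ignored rather than inflating degeneracy. At threshold 0 any observed
#' base is covered (a column with all four bases gives N).
#'
#' @param freqs named numeric vector of A/C/G/T frequencies (one profile
#'   row works).
#' @param minor_freq_threshold minimum frequency for a base to be covered
#'   (default 0.05).
#' @return single IUPAC code character.
#' @export
iupac_consensus <- function(freqs, minor_freq_threshold = 0.05) {
  f <- unlist(freqs)[DNA_BASES]
  if (all(f == 0)) stop("all-gap column: no consensus")
  keep <- names(f)[f >= minor_freq_threshold & f > 0]
  if (length(keep) == 0) keep <- names(f)[which.max(f)]
  IUPAC_CODE_OF[[paste(sort(keep), collapse = "")]]
}

count_degeneracies <- function(seq)
  sum(!strsplit(seq, "", fixed = TRUE)[[1]] %in% DNA_BASES)

#' Enumerate and rank elongations of a seed primer
#'
#' All extensions of the seed within `target_len_range`, growing in the
#' allowed direction(s), are enumerated over the alignment profile; each
#' candidate's sequence is the per-column IUPAC consensus. Candidates are
#' ranked by fewest degenerate positions, then highest mean conservation,
#' then greatest length, then leftmost start (a total order). Candidates
#' exceeding `max_degeneracy` are dropped. A warning (not an error) flags
#' candidates whose 3' end self-overlaps its reverse complement by 8+
#' bases, a crude hairpin/dimer screen.
#'
#' @param alignment character matrix or [seq_records] of aligned rows
#'   (pre-trimmed; see [trim_gappy_columns]).
#' @param seed_interval 0-based half-open `c(start, end)` column interval
#'   of the existing primer.
#' @param direction `"5prime"`, `"3prime"` or `"both"`.
#' @param target_len_range inclusive length bounds (default `c(25, 30)`).
#' @param max_degeneracy maximum degenerate positions (default 3).
#' @param minor_freq_threshold passed to [iupac_consensus].
#' @return data.frame of candidates: `sequence`, `start`, `end` (0-based
#'   half-open), `length`, `n_degenerate`, `mean_conservation`, ranked
#'   best first.
#' @export
elongate_primer <- function(alignment, seed_interval,
                            direction = c("both", "5prime", "3prime"),
                            target_len_range = c(25L, 30L),
                            max_degeneracy = 3L,
                            minor_freq_threshold = 0.05) {
  direction <- match.arg(direction)
  m <- as_alignment_matrix(alignment)
  prof <- alignment_profile(m)
  ncol_aln <- nrow(prof)
  s0 <- seed_interval[1]; e0 <- seed_interval[2]
  stopifnot(s0 >= 0, e0 <= ncol_aln, e0 > s0)
  seed_len <- e0 - s0
  if (seed_len > target_len_range[2])
    stop("seed (", seed_len, " bases) exceeds upper length bound ",
         target_len_range[2])
  lens <- seq(max(target_len_range[1], seed_len), target_len_range[2])
  cands <- list()
  for (L in lens) {
    ext <- L - seed_len
    lefts <- switch(direction,
                    `5prime` = ext, `3prime` = 0L, both = 0:ext)
    for (a in lefts) {
      b <- ext - a
      s <- s0 - a; e <- e0 + b
      if (s < 0 || e > ncol_aln) next
      cols <- (s + 1):e
      code <- try(vapply(cols, function(j)
        iupac_consensus(prof[j, DNA_BASES], minor_freq_threshold), ""),
        silent = TRUE)
      if (inherits(code, "try-error")) next  # all-gap column in range
      seqc <- paste(code, collapse = "")
      cands[[length(cands) + 1L]] <- data.frame(
        sequence = seqc, start = s, end = e, length = L,
        n_degenerate = count_degeneracies(seqc),
        mean_conservation = mean(prof$conservation[cols]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0)
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_degenerate = integer(), mean_conservation = numeric()))
  out <- do.call(rbind, cands)
  out <- out[out$n_degenerate <= max_degeneracy, , drop = FALSE]
  out <- out[order(out$n_degenerate, -out$mean_conservation, -out$length,
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  hairpin <- vapply(out$sequence, function(s) {
    n <- nchar(s)
    if (n < 8) return(FALSE)
    tail8 <- substr(s, n - 7, n)
    grepl(revcomp(tail8), s, fixed = TRUE)
  }, TRUE)
  if (any(hairpin))
    warning(sum(hairpin), " candidate(s) show 8+ base reverse-complement ",
            "self-overlap (possible hairpin/dimer); check before ordering")
  out
}
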