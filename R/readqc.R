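# Quality and length filtering plus exact dereplication. No OTU clustering:
# with complex communities of closely related species at skewed abundances,
# unique sequences are kept as-is and assigned individually.

#' Mean Phred score of a read
#'
#' Error-probability averaging: `Q = -10 log10( mean_i 10^(-q_i/10) )`,
#' i.e. the quality of the mean per-base error probability. This is the
#' "average quality" semantics of standard read-filtering tools and is
#' stricter than the arithmetic mean of Phred scores on mixed-quality
#' reads.
#'
#' @param record one-row [seq_records] data.frame (or any row with a `qual`
#'   list-column).
#' @return mean Phred score (float).
#' @examples
#' r <- seq_records("r1", "ACGT", list(c(20L, 20L, 20L, 20L)))
#' mean_phred(r[1, ])  # 20
#' @export
mean_phred <- function(record) {
  q <- record$qual[[1]]
  if (is.null(q) || length(q) == 0)
    stop("mean_phred: record ", record$id, " has no quality")
  -10 * log10(mean(10^(-q / 10)))
}

#' Filter reads by mean quality and marker length window
#'
#' Keeps a read iff its mean Phred score is strictly greater than
#' `config$min_mean_phred` and its length falls inside the marker's closed
#' length window (172-212 bp for the eDNA marker, 520-580 bp for the
#' barcoding marker by default).
#'
#' @param records a [seq_records] data.frame of primer-trimmed inserts.
#' @param marker `"edna"` or `"barcode"`.
#' @param config a [run_config].
#' @return list with `kept` ([seq_records]) and `tally`: named counts of
#'   rejections by cause (`short`, `long`, `low_quality`) plus `kept`.
#' @export
filter_reads <- function(records, marker, config = run_config()) {
  win <- switch(marker,
                edna = config$length_window_edna,
                barcode = config$length_window_barcode,
                stop("unknown marker: ", marker))
  len <- nchar(records$seq)
  mq <- vapply(seq_len(nrow(records)),
               function(i) mean_phred(records[i, ]), 0)
  short <- len < win[1]
  long <- len > win[2]
  lowq <- !short & !long & !(mq > config$min_mean_phred)
  keep <- !short & !long & !lowq
  out <- records[keep, , drop = FALSE]
  class(out) <- c("seq_records", "data.frame")
  list(kept = out,
       tally = c(kept = sum(keep), short = sum(short), long = sum(long),
                 low_quality = sum(lowq)))
}

#' Exact dereplication of identical sequences
#'
#' Collapses reads by exact string equality (N and degeneracy codes are
#' literal characters). Output is ordered by size descending, ties broken
#' by first occurrence, in the style of standard dereplication tools.
#'
#' @param records a [seq_records] data.frame of forward-sense inserts.
#' @return data.frame of class `derep_set`: `uniq_id`, `seq`, `size`, and a
#'   list-column `member_ids`.
#' @export
dereplicate <- function(records) {
  if (nrow(records) == 0) {
    out <- data.frame(uniq_id = character(), seq = character(),
                      size = integer(), stringsAsFactors = FALSE)
    out$member_ids <- list()
    class(out) <- c("derep_set", "data.frame")
    return(out)
  }
  first <- !duplicated(records$seq)
  uniq <- records$seq[first]
  grp <- match(records$seq, uniq)
  size <- tabulate(grp, nbins = length(uniq))
  ord <- order(-size, seq_along(uniq))
  out <- data.frame(uniq_id = sprintf("uniq%05d", seq_along(uniq)),
                    seq = uniq[ord], size = size[ord],
                    stringsAsFactors = FALSE)
  out$member_ids <- lapply(ord, function(g) records$id[grp == g])
  class(out) <- c("derep_set", "data.frame")
  out
}

#' Write a dereplicated set as FASTA with `;size=N` annotations
#' @param derep a [dereplicate] result.
#' @param path output path.
#' @export
write_derep_fasta <- function(derep, path) {
  writeLines(as.vector(rbind(
    sprintf(">%s;size=%d", derep$uniq_id, derep$size), derep$seq)), path)
  invisible(path)
}
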