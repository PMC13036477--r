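# Dual-index demultiplexing by bounded edit distance. A read is assigned to
# a sample when both of that sample's 20-base indexes are found — one in
# the leading window, one (reverse-complemented) in the trailing window —
# each within `tol_index` edits, in either read orientation. Ties on the
# summed distance across samples are never broken arbitrarily: the read is
# left unassigned as ambiguous. This mirrors the conservative defaults of
# index demultiplexers for long noisy reads.

# search window: index length + tolerance + 5 bases of adapter slop
index_window <- function(tol) 20L + tol + 5L

#' Demultiplex pooled reads by dual 20-base indexes
#'
#' @param reads a [seq_records] data.frame of pooled reads.
#' @param sheet a [sample_sheet].
#' @param tol_index maximum edit distance per index (default 2).
#' @param tol_primer maximum edit distance for primer location (default 3);
#'   primers may contain IUPAC degeneracy codes.
#' @param primers named list per marker, each `c(f = ..., r = ...)` giving
#'   the forward and reverse primer (the reverse primer as its own 5'-3'
#'   sequence, i.e. the reverse complement of its binding site). `NULL`
#'   skips primer trimming.
#' @return list with `results`: data.frame (read_id, sample_id, reason,
#'   orientation, insert, primer_trimmed) carrying index- and
#'   primer-trimmed inserts in forward sense plus a `qual` list-column, and
#'   `summary`: per-sample assignment counts including `n_ambiguous` and
#'   `n_no_match` rows.
#' @export
demultiplex <- function(reads, sheet, tol_index = 2L, tol_primer = 3L,
                        primers = NULL) {
  if (nrow(sheet) == 0) stop("empty sample sheet")
  stopifnot(tol_index >= 0, tol_primer >= 0)
  n <- nrow(reads)
  uf <- unique(sheet$index_f)
  ur_rc <- unique(revcomp(sheet$index_r))
  ur <- unique(sheet$index_r)
  win <- index_window(tol_index)

  scan <- function(seqs) {
    lead <- substr(seqs, 1, win)
    trail <- substr(seqs, pmax(1, nchar(seqs) - win + 1L), nchar(seqs))
    sf <- .cpp_index_scan(lead, uf)
    sr <- .cpp_index_scan(trail, ur_rc)
    list(df = sf$dist, ef = sf$end,                      # end of index_f in lead
         dr = sr$dist, sr_start = sr$start,              # start of rc(index_r) in trail
         trail_off = pmax(1, nchar(seqs) - win + 1L) - 1L)
  }
  fwd <- scan(reads$seq)
  rc_seq <- revcomp(reads$seq)
  rev <- scan(rc_seq)

  fi <- match(sheet$index_f, uf)
  ri <- match(sheet$index_r, ur)
  big <- 1000L
  dcap <- function(d) ifelse(d > tol_index, big, d)
  tot_f <- dcap(fwd$df)[, fi, drop = FALSE] + dcap(fwd$dr)[, ri, drop = FALSE]
  tot_r <- dcap(rev$df)[, fi, drop = FALSE] + dcap(rev$dr)[, ri, drop = FALSE]
  best_per_read <- pmin(apply(tot_f, 1, min), apply(tot_r, 1, min))

  sample_id <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  insert <- character(n)
  qual <- vector("list", n)
  trimmed <- rep(FALSE, n)

  for (i in seq_len(n)) {
    b <- best_per_read[i]
    if (b >= big) { reason[i] <- "no_match"; insert[i] <- reads$seq[i]; qual[i] <- list(reads$qual[[i]]); next }
    hit_f <- which(tot_f[i, ] == b)
    hit_r <- which(tot_r[i, ] == b)
    hits <- unique(c(hit_f, hit_r))
    if (length(hits) > 1) { reason[i] <- "ambiguous"; insert[i] <- reads$seq[i]; qual[i] <- list(reads$qual[[i]]); next }
    s <- hits[1]
    # orientation: forward preferred on equal distance
    use_fwd <- length(hit_f) == 1
    orientation[i] <- if (use_fwd) "forward" else "reverse"
    sample_id[i] <- sheet$sample_id[s]
    seqi <- if (use_fwd) reads$seq[i] else rc_seq[i]
    qi <- reads$qual[[i]]
    if (!use_fwd && !is.null(qi)) qi <- rev(qi)
    sc <- if (use_fwd) fwd else rev
    from <- sc$ef[i, fi[s]] + 1L
    to <- sc$trail_off[i] + sc$sr_start[i, ri[s]] - 1L
    if (to < from) { from <- 1L; to <- nchar(seqi) }
    insert[i] <- substr(seqi, from, to)
    if (!is.null(qi)) qual[[i]] <- qi[from:to]
  }

  # primer trimming on assigned reads
  if (!is.null(primers)) {
    marker_of <- sheet$marker[match(sample_id, sheet$sample_id)]
    for (i in which(!is.na(sample_id))) {
      p <- primers[[marker_of[i]]]
      if (is.null(p)) next
      ins <- insert[i]
      plen_f <- nchar(p[["f"]]); plen_r <- nchar(p[["r"]])
      ok_f <- ok_r <- FALSE
      head_w <- substr(ins, 1, min(nchar(ins), plen_f + tol_primer + 5L))
      hf <- infix_search(p[["f"]], head_w, iupac = TRUE)
      if (hf$dist[1] <= tol_primer) { ok_f <- TRUE; f_cut <- hf$end[1] }
      tail_from <- max(1L, nchar(ins) - (plen_r + tol_primer + 5L) + 1L)
      tail_w <- substr(ins, tail_from, nchar(ins))
      hr <- infix_search(revcomp(p[["r"]]), tail_w, iupac = TRUE)
      if (hr$dist[1] <= tol_primer) { ok_r <- TRUE; r_cut <- tail_from + hr$start[1] - 2L }
      if (ok_f && ok_r && r_cut >= f_cut + 1L) {
        qi <- qual[[i]]
        insert[i] <- substr(ins, f_cut + 1L, r_cut)
        if (!is.null(qi)) qual[[i]] <- qi[(f_cut + 1L):r_cut]
        trimmed[i] <- TRUE
      }
    }
  }

  results <- data.frame(read_id = reads$id, sample_id = sample_id,
                        reason = reason, orientation = orientation,
                        insert = insert, primer_trimmed = trimmed,
                        stringsAsFactors = FALSE)
  results$qual <- qual
  counts <- table(factor(sample_id, levels = sheet$sample_id))
  summary <- data.frame(sample_id = c(sheet$sample_id, "AMBIGUOUS", "NO_MATCH"),
                        n_reads = c(as.integer(counts),
                                    sum(reason == "ambiguous", na.rm = TRUE),
                                    sum(reason == "no_match", na.rm = TRUE)),
                        stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}

#' Assigned inserts of one sample as sequence records
#'
#' @param demux a [demultiplex] result.
#' @param sample_id sample to extract.
#' @return a [seq_records] data.frame of forward-sense inserts.
#' @export
demux_sample_records <- function(demux, sample_id) {
  r <- demux$results
  keep <- !is.na(r$sample_id) & r$sample_id == sample_id & nchar(r$insert) > 0
  seq_records(r$read_id[keep], r$insert[keep], r$qual[keep])
}
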