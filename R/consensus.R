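# Consensus barcoding from noisy long reads, one specimen at a time:
# greedy centroid clustering, medoid draft selection, then up to three
# rounds of align-stack-vote polishing with majority calls per column and
# an end-trim of weakly supported terminal columns (an algorithmic
# surrogate for the manual removal of divergent consensus ends).

#' Greedy centroid clustering of reads
#'
#' Reads are visited by length descending; each read joins the first
#' cluster whose centroid it matches at or above `identity_threshold`,
#' otherwise it founds a new cluster. Both orientations are checked and
#' reads are stored re-oriented to the centroid strand. The membership
#' statistic is gap-free identity (matches over aligned non-gap columns):
#' with noisy long reads, indel columns would otherwise push genuinely
#' conspecific reads below the threshold, while templates tens of percent
#' apart stay clearly separated either way.
#'
#' @param records a [seq_records] data.frame; at least 3 reads (fewer is a
#'   failure status, since low-coverage consensus is unreliable).
#' @param identity_threshold fraction in (0, 1]; default 0.90.
#' @return list with `clusters` (list of [seq_records], ordered by size
#'   descending then by founding order) and `status` (`"ok"` or
#'   `"insufficient reads"`).
#' @export
cluster_reads <- function(records, identity_threshold = 0.90) {
  if (nrow(records) < 3)
    return(list(clusters = list(), status = "insufficient reads"))
  ord <- order(-nchar(records$seq), seq_len(nrow(records)))
  centroids <- character(0)
  assign_to <- integer(nrow(records))
  oriented <- records$seq
  gapfree_identity <- function(al) {
    gaps <- (nchar(al$aligned_query) - nchar(gsub("-", "", al$aligned_query))) +
      (nchar(al$aligned_subject) - nchar(gsub("-", "", al$aligned_subject)))
    nongap <- al$alignment_length - gaps
    if (nongap > 0) 100 * al$matches / nongap else 0
  }
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      fw <- align_identity(records$seq[i], centroids[ci])
      rc <- align_identity(revcomp(records$seq[i]), centroids[ci])
      use_rc <- rc$score > fw$score
      best <- if (use_rc) rc else fw
      # guard: a high-identity sliver of a long read is not a cluster match
      if (gapfree_identity(best) >= 100 * identity_threshold &&
          best$alignment_length >= 0.6 * min(nchar(records$seq[i]), nchar(centroids[ci]))) {
        assign_to[i] <- ci
        if (use_rc) oriented[i] <- revcomp(records$seq[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, records$seq[i])
      assign_to[i] <- length(centroids)
    }
  }
  clusters <- lapply(seq_along(centroids), function(ci) {
    keep <- which(assign_to == ci)
    out <- records[keep, , drop = FALSE]
    out$seq <- oriented[keep]
    class(out) <- c("seq_records", "data.frame")
    out
  })
  sizes <- vapply(clusters, nrow, 0L)
  list(clusters = clusters[order(-sizes, seq_along(clusters))], status = "ok")
}

# stack one read's global alignment onto the draft's columns
stack_alignment <- function(read_seq, draft) {
  al <- align_identity(read_seq, draft, type = "global")
  pa <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
  sa <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
  scol <- cumsum(sa != "-")
  nonins <- sa != "-"
  ins <- !nonins
  runs <- NULL
  if (any(ins)) {
    key <- scol[ins]
    runs <- vapply(split(pa[ins], key), paste, "", collapse = "")
  }
  list(col = scol[nonins], base = pa[nonins], ins = runs)
}

#' Polish a cluster into a consensus sequence
#'
#' The draft is the medoid read (minimal summed edit distance to up to 30
#' sampled cluster mates). Up to three polishing rounds follow: every read
#' is globally aligned to the draft (affine gaps), alignment columns are
#' stacked, and each column is called by majority vote over
#' \{A, C, G, T, deletion\}; an insertion is accepted when more than half
#' of the reads carry one at that junction (most common inserted string,
#' ties broken lexicographically). Polishing stops early when a round
#' leaves the draft unchanged. Finally, terminal columns where fewer than
#' half of the reads have an aligned base are trimmed.
#'
#' @param cluster a non-empty [seq_records] data.frame of same-strand reads.
#' @param max_rounds maximum polishing rounds (default 3).
#' @param seed seed for the medoid subsample.
#' @return list of class `consensus_result`: `consensus` (string),
#'   `n_supporting_reads`, `cluster_fraction` (filled by the caller, `NA`
#'   here), `trimmed_left`, `trimmed_right`, `converged`.
#' @export
polish <- function(cluster, max_rounds = 3L, seed = 1L) {
  n <- nrow(cluster)
  stopifnot(n >= 1)
  if (n == 1) {
    return(structure(list(consensus = cluster$seq[1], n_supporting_reads = 1L,
                          cluster_fraction = NA_real_, trimmed_left = 0L,
                          trimmed_right = 0L, converged = TRUE),
                     class = "consensus_result"))
  }
  set.seed(seed)
  mates <- if (n > 30) sample.int(n, 30) else seq_len(n)
  # same-cluster reads differ by at most ~2x the per-read error rate;
  # a 25% band is ample and keeps the medoid search cheap
  cap <- as.integer(0.25 * max(nchar(cluster$seq)))
  dsum <- vapply(seq_len(n), function(i) {
    sum(.cpp_edit_distance(rep(cluster$seq[i], length(mates)),
                           cluster$seq[mates], cap))
  }, 0)
  draft <- cluster$seq[which.min(dsum)]

  vote_profile <- function(draft) {
    L <- nchar(draft)
    votes <- matrix(0L, L, 5, dimnames = list(NULL, c("A", "C", "G", "T", "-")))
    ins_runs <- vector("list", L + 1L)
    for (i in seq_len(n)) {
      st <- stack_alignment(cluster$seq[i], draft)
      ok <- st$base %in% colnames(votes)
      idx <- cbind(st$col[ok], match(st$base[ok], colnames(votes)))
      votes[idx] <- votes[idx] + 1L
      if (!is.null(st$ins)) {
        for (k in seq_along(st$ins)) {
          j <- as.integer(names(st$ins)[k]) + 1L  # slot after draft col j-1
          ins_runs[[j]] <- c(ins_runs[[j]], st$ins[k])
        }
      }
    }
    list(votes = votes, ins_runs = ins_runs, L = L)
  }
  call_cols <- function(votes) {
    # base wins ties against deletion; bases tie-break alphabetically
    apply(votes, 1, function(v) {
      nm <- colnames(votes)[which(v == max(v))]
      if (length(nm) > 1) nm <- setdiff(nm, "-")[1] %||% "-"
      nm[1]
    })
  }
  build_consensus <- function(prof) {
    calls <- call_cols(prof$votes)
    pieces <- character(0)
    for (j in 0:prof$L) {
      runs <- prof$ins_runs[[j + 1L]]
      if (!is.null(runs) && length(runs) > n / 2) {
        tb <- table(runs)
        pieces <- c(pieces, sort(names(tb)[tb == max(tb)])[1])
      }
      if (j < prof$L && calls[j + 1L] != "-") pieces <- c(pieces, calls[j + 1L])
    }
    paste(pieces, collapse = "")
  }

  converged <- FALSE
  prof <- NULL
  for (round in seq_len(max_rounds)) {
    prof <- vote_profile(draft)
    newdraft <- build_consensus(prof)
    if (newdraft == draft) { converged <- TRUE; break }
    draft <- newdraft
  }
  if (!converged) prof <- vote_profile(draft)  # profile for the final draft

  # end trim: strip terminal draft columns where fewer than half of the
  # reads contribute an aligned base
  base_cov <- rowSums(prof$votes[, 1:4, drop = FALSE])
  supported <- which(base_cov >= n / 2)
  if (length(supported) == 0) {
    consensus <- draft; tl <- 0L; tr <- 0L
  } else {
    tl <- supported[1] - 1L
    tr <- nchar(draft) - supported[length(supported)]
    consensus <- substr(draft, tl + 1L, nchar(draft) - tr)
  }
  structure(list(consensus = consensus, n_supporting_reads = n,
                 cluster_fraction = NA_real_, trimmed_left = as.integer(tl),
                 trimmed_right = as.integer(tr), converged = converged),
            class = "consensus_result")
}

#' Consensus barcode for one specimen
#'
#' Clusters the specimen's filtered reads, polishes the largest cluster,
#' and reports the supporting-read fraction. Specimens with more than
#' `max_reads` reads are subsampled (seeded) to bound runtime.
#'
#' @param records a [seq_records] data.frame of one specimen's reads.
#' @param min_reads minimum reads required (default 3).
#' @param max_reads subsampling cap (default 300).
#' @param identity_threshold clustering threshold (default 0.90).
#' @param seed integer RNG seed.
#' @return a `consensus_result` (see [polish]) with `cluster_fraction`
#'   filled, or a list with `status = "insufficient reads"`.
#' @export
consensus_specimen <- function(records, min_reads = 3L, max_reads = 300L,
                               identity_threshold = 0.90, seed = 1L) {
  if (nrow(records) < min_reads || nrow(records) < 3)
    return(list(status = "insufficient reads",
                n_supporting_reads = nrow(records)))
  set.seed(seed)
  if (nrow(records) > max_reads) {
    records <- records[sample.int(nrow(records), max_reads), , drop = FALSE]
    class(records) <- c("seq_records", "data.frame")
  }
  cl <- cluster_reads(records, identity_threshold)
  top <- cl$clusters[[1]]
  res <- polish(top, seed = seed)
  res$cluster_fraction <- nrow(top) / nrow(records)
  res$status <- "ok"
  res
}
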