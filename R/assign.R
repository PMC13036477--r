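# Best-hit taxonomic assignment: the direct BLASTn-style approach
# re-implemented as a k-mer prescreen followed by local alignment. One best
# hit per query (maximal score, deterministic tie-breaking), then the hit
# is tested against each percent-identity threshold independently.

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# k-mer index of a reference db: environment kmer -> integer record indices
build_kmer_index <- function(db, k = 11L) {
  env <- new.env(hash = TRUE, size = 4L * nrow(db) * 600L)
  for (i in seq_len(nrow(db))) {
    for (km in seq_kmers(db$seq[i], k)) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  attr(env, "k") <- k
  env
}

#' Rank reference candidates by shared k-mers
#'
#' Counts distinct k-mers shared between the query (both orientations) and
#' each reference record; returns the `top_n` accessions ordered by count
#' descending, accession ascending.
#'
#' @param query nucleotide string of length at least `k`.
#' @param db a `reference_db`.
#' @param k k-mer size (default 11).
#' @param top_n number of candidates to keep (default 50).
#' @param index optional prebuilt index from an earlier call (attribute
#'   `k` must match); built on the fly otherwise.
#' @return character vector of candidate accessions (possibly empty).
#' @export
kmer_prescreen <- function(query, db, k = 11L, top_n = 50L, index = NULL) {
  stopifnot(nchar(query) >= k)
  if (is.null(index)) index <- build_kmer_index(db, k)
  kms <- unique(c(seq_kmers(query, k), seq_kmers(revcomp(query), k)))
  hits <- integer(nrow(db))
  for (km in kms) {
    ids <- index[[km]]
    if (!is.null(ids)) hits[ids] <- hits[ids] + 1L
  }
  cand <- which(hits > 0)
  if (length(cand) == 0) return(character(0))
  ord <- order(-hits[cand], db$accession[cand])
  db$accession[cand[ord]][seq_len(min(top_n, length(cand)))]
}

#' Best-hit assignment of a query at dual identity thresholds
#'
#' Prescreened candidates are aligned locally in both query orientations;
#' the best hit maximises score, with ties broken by higher identity, then
#' provenance `local` before `base`, then accession ascending. Hits whose
#' alignment covers less than `min_aln_frac` of the query are discarded as
#' spurious short local matches. The single best hit is then tested against
#' each threshold independently.
#'
#' @param query nucleotide string.
#' @param db a `reference_db` (non-empty).
#' @param thresholds percent-identity cutoffs (default `c(95, 99)`).
#' @param k,top_n,index prescreen parameters, see [kmer_prescreen].
#' @param min_aln_frac minimum alignment length as a fraction of query
#'   length (default 0.8).
#' @return list with `hit` (NULL, or a one-row data.frame with accession,
#'   percent_identity, alignment_length, score, lineage ranks, provenance)
#'   and `pass`: named logical per threshold.
#' @export
best_hit <- function(query, db, thresholds = c(95, 99), k = 11L, top_n = 50L,
                     index = NULL, min_aln_frac = 0.8) {
  if (nrow(db) == 0) stop("empty reference database")
  pass <- setNames(rep(FALSE, length(thresholds)),
                   format(thresholds, trim = TRUE))
  cand <- kmer_prescreen(query, db, k, top_n, index)
  if (length(cand) == 0) return(list(hit = NULL, pass = pass))
  rows <- match(cand, db$accession)
  best <- NULL
  for (i in rows) {
    fw <- align_identity(query, db$seq[i])
    rc <- align_identity(revcomp(query), db$seq[i])
    al <- if (rc$score > fw$score) rc else fw
    if (al$alignment_length < min_aln_frac * nchar(query)) next
    cur <- list(i = i, score = al$score, pid = al$percent_identity,
                len = al$alignment_length)
    if (is.null(best)) { best <- cur; next }
    better <- cur$score > best$score ||
      (cur$score == best$score && cur$pid > best$pid) ||
      (cur$score == best$score && cur$pid == best$pid &&
         db$provenance[cur$i] == "local" && db$provenance[best$i] == "base") ||
      (cur$score == best$score && cur$pid == best$pid &&
         db$provenance[cur$i] == db$provenance[best$i] &&
         db$accession[cur$i] < db$accession[best$i])
    if (better) best <- cur
  }
  if (is.null(best)) return(list(hit = NULL, pass = pass))
  hit <- cbind(data.frame(accession = db$accession[best$i],
                          percent_identity = best$pid,
                          alignment_length = best$len,
                          score = best$score, stringsAsFactors = FALSE),
               db[best$i, RANKS, drop = FALSE],
               data.frame(provenance = db$provenance[best$i],
                          stringsAsFactors = FALSE))
  rownames(hit) <- NULL
  for (t in seq_along(thresholds)) pass[t] <- best$pid >= thresholds[t]
  list(hit = hit, pass = pass)
}

#' Assign every unique sequence of a dereplicated set
#'
#' Queries are the dereplicated unique sequences; counts are re-expanded by
#' `size` downstream. The k-mer index is built once.
#'
#' @param derep a [dereplicate] result (or data.frame with `uniq_id`,
#'   `seq`, `size`).
#' @param db a `reference_db`.
#' @param thresholds percent-identity cutoffs.
#' @param ... passed to [best_hit].
#' @return hit table data.frame: query_id, size, accession, identity,
#'   aln_len, score, the seven rank columns, provenance, and one logical
#'   `pass<threshold>` column per threshold; unassigned queries carry NA
#'   accession and FALSE passes.
#' @export
assign_queries <- function(derep, db, thresholds = c(95, 99), ...) {
  index <- build_kmer_index(db)
  rows <- lapply(seq_len(nrow(derep)), function(i) {
    bh <- best_hit(derep$seq[i], db, thresholds, index = index, ...)
    base <- data.frame(query_id = derep$uniq_id[i], size = derep$size[i],
                       stringsAsFactors = FALSE)
    if (is.null(bh$hit)) {
      hit <- data.frame(accession = NA_character_, percent_identity = NA_real_,
                        alignment_length = NA_integer_, score = NA_real_,
                        stringsAsFactors = FALSE)
      lin <- as.data.frame(as.list(setNames(rep(NA_character_, length(RANKS)),
                                            RANKS)), stringsAsFactors = FALSE)
      hit <- cbind(hit, lin, data.frame(provenance = NA_character_))
    } else hit <- bh$hit
    ps <- as.data.frame(as.list(bh$pass))
    names(ps) <- paste0("pass", names(bh$pass))
    cbind(base, hit, ps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
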