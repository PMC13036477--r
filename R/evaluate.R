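# Accuracy evaluation against a locality checklist. A taxon assigned from
# eDNA is "correct" when it is on the checklist of species (or genera)
# confirmed for the study area, and "incorrect" otherwise — the operational
# definition used for field validation, where no per-read truth exists.
# Database comparisons are summarised as risk ratios of correct-assignment
# proportions with log-normal Wald confidence intervals.

#' Locality checklist
#'
#' @param species character vector of confirmed species binomials.
#' @param genera optional character vector of confirmed genera; genera of
#'   `species` are always included.
#' @param other_expected optional non-target taxa expected in the system.
#' @return list of class `checklist`.
#' @export
checklist <- function(species, genera = NULL, other_expected = NULL) {
  species <- unique(species)
  genera <- unique(c(genera, vapply(strsplit(species, " "), `[`, "", 1)))
  structure(list(species = species, genera = genera,
                 other_expected = other_expected %||% character(0)),
            class = "checklist")
}

#' Read a checklist TSV (columns `species`, optional `genus`)
#' @param path TSV path.
#' @return a [checklist].
#' @export
read_checklist <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  checklist(df$species, df$genus)
}

#' Score a count table against a checklist
#'
#' Reads assigned to the target class are split into correct and incorrect
#' by checklist membership at the table's rank. Percentages use the stated
#' denominators: class reads for correctness, all above-threshold reads for
#' the class share.
#'
#' @param table a `taxon_count_table` (all classes retained).
#' @param checklist a [checklist].
#' @param target_class class name whose assignments are scored (default
#'   `"Amphibia"`).
#' @return list with `n_total_reads_above_threshold`, `n_target_reads`,
#'   `pct_target_of_total`, `n_correct`, `n_incorrect`, `pct_correct`,
#'   `taxa_correct`, `taxa_incorrect`.
#' @export
score_assignments <- function(table, checklist, target_class = "Amphibia") {
  if (length(table) == 0 || sum(table) == 0) stop("empty count table")
  taxa <- attr(table, "taxa")
  rank <- attr(table, "rank")
  totals <- colSums(table)
  n_total <- sum(totals)
  is_target <- !is.na(taxa$class) & taxa$class == target_class
  ref <- if (rank == "species") checklist$species else checklist$genera
  correct <- is_target & taxa$taxon %in% ref
  n_target <- sum(totals[is_target])
  n_correct <- sum(totals[correct])
  list(n_total_reads_above_threshold = n_total,
       n_target_reads = n_target,
       pct_target_of_total = 100 * n_target / n_total,
       n_correct = n_correct,
       n_incorrect = n_target - n_correct,
       pct_correct = if (n_target > 0) 100 * n_correct / n_target else NA_real_,
       taxa_correct = taxa$taxon[correct],
       taxa_incorrect = taxa$taxon[is_target & !correct])
}

#' Risk ratio of two proportions with a log-normal Wald interval
#'
#' `RR = (x1/n1) / (x2/n2)`; the confidence interval is
#' `exp( ln RR +/- z * sqrt(1/x1 - 1/n1 + 1/x2 - 1/n2) )` with
#' `z = qnorm(1 - (1 - conf)/2)`.
#'
#' @param x1,n1 correct count and group size of group 1.
#' @param x2,n2 correct count and group size of group 2; `x2 = 0` is an
#'   error (the ratio is undefined; apply an explicit continuity correction
#'   upstream if needed).
#' @param conf confidence level (default 0.95).
#' @return list with `rr`, `ci_low`, `ci_high`.
#' @examples
#' risk_ratio(49552, 53225, 5867, 48091)  # RR 7.63, CI 7.45-7.82
#' @export
risk_ratio <- function(x1, n1, x2, n2, conf = 0.95) {
  stopifnot(x1 > 0, x1 <= n1, x2 <= n2, conf > 0, conf < 1)
  if (x2 == 0) stop("x2 = 0: risk ratio undefined without continuity correction")
  rr <- (x1 / n1) / (x2 / n2)
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
  list(rr = rr, ci_low = exp(log(rr) - z * se), ci_high = exp(log(rr) + z * se))
}

#' Compare a base and an augmented database over thresholds and ranks
#'
#' Both hit sets must come from the same query set. For every (rank,
#' threshold) the correct-assignment proportions of the two databases are
#' compared as a risk ratio (combined over base), and detected checklist
#' species are counted per database. A base database with zero correct
#' reads receives an explicit continuity count of 1 so the ratio stays
#' defined (flagged by `ci_low`/`ci_high` spanning a wide range).
#'
#' @param hits_base,hits_combined named per-sample lists (or `sample_id`
#'   data.frames) of [assign_queries] tables for the base and the
#'   augmented database.
#' @param sheet a [sample_sheet].
#' @param checklist a [checklist].
#' @param thresholds identity cutoffs (default `c(95, 99)`).
#' @param ranks ranks to score (default species and genus).
#' @param target_class scored class (default `"Amphibia"`).
#' @return list of class `accuracy_report`: `scores` data.frame (database,
#'   rank, threshold, read counts and percentages, species detected) and
#'   `comparisons` data.frame (rank, threshold, rr, ci_low, ci_high).
#' @export
compare_databases <- function(hits_base, hits_combined, sheet, checklist,
                              thresholds = c(95, 99),
                              ranks = c("species", "genus"),
                              target_class = "Amphibia") {
  qset <- function(h) {
    if (is.data.frame(h)) h <- split(h, h$sample_id)
    lapply(h, function(x) sort(x$query_id))
  }
  if (!identical(qset(hits_base), qset(hits_combined)))
    stop("hit tables were not produced from the same query set")
  scores <- list(); comparisons <- list()
  for (th in thresholds) for (rk in ranks) {
    sc <- lapply(list(base = hits_base, combined = hits_combined), function(h) {
      tab <- tabulate_hits(h, sheet, rank = rk, threshold = th)
      s <- score_assignments(tab, checklist, target_class)
      sp_tab <- if (rk == "species") tab else
        tabulate_hits(h, sheet, rank = "species", threshold = th)
      sp_tot <- colSums(sp_tab)
      s$n_species_detected <- sum(names(sp_tot) %in% checklist$species & sp_tot > 0)
      s
    })
    for (dbn in names(sc))
      scores[[paste(dbn, rk, th)]] <- data.frame(
        database = dbn, rank = rk, threshold = th,
        n_total_reads_above_threshold = sc[[dbn]]$n_total_reads_above_threshold,
        n_target_reads = sc[[dbn]]$n_target_reads,
        pct_target_of_total = sc[[dbn]]$pct_target_of_total,
        n_correct = sc[[dbn]]$n_correct,
        pct_correct = sc[[dbn]]$pct_correct,
        n_species_detected = sc[[dbn]]$n_species_detected,
        stringsAsFactors = FALSE)
    rr <- if (sc$combined$n_target_reads > 0 && sc$base$n_target_reads > 0 &&
              sc$combined$n_correct > 0) {
      risk_ratio(sc$combined$n_correct, sc$combined$n_target_reads,
                 min(max(1L, sc$base$n_correct), sc$base$n_target_reads),
                 sc$base$n_target_reads)
    } else list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    comparisons[[paste(rk, th)]] <- data.frame(
      rank = rk, threshold = th, rr = rr$rr,
      ci_low = rr$ci_low, ci_high = rr$ci_high, stringsAsFactors = FALSE)
  }
  structure(list(scores = do.call(rbind, scores),
                 comparisons = do.call(rbind, comparisons)),
            class = "accuracy_report")
}
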