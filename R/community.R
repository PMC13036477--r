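# From hit tables to ecology: per-sample taxon count tables at a stated
# rank and threshold, the noise floor (counts <= 5 zeroed per sample), the
# negative-control taxon filter, replicate-aware detection statistics and
# elevational summaries. Pipeline order is fixed: tabulate -> noise floor
# -> control removal.

#' Tabulate assigned reads into a sample x taxon count table
#'
#' Each cell sums the dereplicated sizes of a sample's unique sequences
#' whose best hit passes the threshold and resolves to that taxon at the
#' requested rank. All classes (including non-target bycatch) are kept so
#' that class shares can be computed downstream.
#'
#' @param hits named list of per-sample hit tables from [assign_queries]
#'   (names are sample ids), or a single hit table with a `sample_id`
#'   column.
#' @param sheet a [sample_sheet].
#' @param rank `"species"` or `"genus"`.
#' @param threshold one of the thresholds the hits were tested against.
#' @return matrix of integer counts (samples x taxa) of class
#'   `taxon_count_table`, with attributes `rank`, `threshold` and `taxa`
#'   (data.frame mapping taxon name to class).
#' @export
tabulate_hits <- function(hits, sheet, rank = c("species", "genus"),
                          threshold = 95) {
  rank <- match.arg(rank)
  if (is.data.frame(hits)) {
    stopifnot("sample_id" %in% names(hits))
    hits <- split(hits, hits$sample_id)
  }
  unknown <- setdiff(names(hits), sheet$sample_id)
  if (length(unknown))
    stop("sample(s) in hits absent from sheet: ", paste(unknown, collapse = ", "))
  passcol <- paste0("pass", format(threshold, trim = TRUE))
  taxa_map <- list()
  cells <- list()
  for (sid in names(hits)) {
    h <- hits[[sid]]
    stopifnot(passcol %in% names(h))
    keep <- !is.na(h$accession) & h[[passcol]] & h[[rank]] != "UNKNOWN"
    if (!any(keep)) next
    agg <- tapply(h$size[keep], h[[rank]][keep], sum)
    cells[[sid]] <- agg
    cls <- tapply(h$class[keep], h[[rank]][keep], `[`, 1)
    taxa_map[[sid]] <- cls
  }
  taxa <- sort(unique(unlist(lapply(cells, names))))
  tab <- matrix(0L, nrow = length(hits), ncol = length(taxa),
                dimnames = list(names(hits), taxa))
  for (sid in names(cells))
    tab[sid, names(cells[[sid]])] <- as.integer(cells[[sid]])
  cls <- setNames(rep(NA_character_, length(taxa)), taxa)
  for (sid in names(taxa_map)) {
    m <- taxa_map[[sid]]
    cls[names(m)[is.na(cls[names(m)])]] <- m[is.na(cls[names(m)])]
  }
  structure(tab, rank = rank, threshold = threshold,
            taxa = data.frame(taxon = taxa, class = unname(cls),
                              stringsAsFactors = FALSE),
            class = c("taxon_count_table", class(tab)))
}

#' Zero out sub-noise-floor counts
#'
#' Per-sample taxon read counts less than or equal to `floor` are regarded
#' as noise (index cross-talk, trace contamination) and set to 0.
#'
#' @param table a `taxon_count_table` (or plain integer matrix).
#' @param floor integer noise floor (default 5; a count of exactly 5 is
#'   zeroed).
#' @return the filtered table, attributes preserved.
#' @export
apply_noise_floor <- function(table, floor = 5L) {
  out <- table
  out[out <= floor] <- 0L
  out
}

#' Remove taxa present in negative controls
#'
#' Any taxon with a nonzero count in any control sample (after the noise
#' floor) is deleted from every sample; control rows are dropped from the
#' output. Run this after [apply_noise_floor]: trace control counts at or
#' below the floor do not trigger removal.
#'
#' @param table a `taxon_count_table`.
#' @param control_sample_ids character vector of control sample ids; must
#'   all be rows of the table.
#' @return list with `table` (controls dropped, contaminant taxa removed)
#'   and `removed_taxa`.
#' @export
remove_control_taxa <- function(table, control_sample_ids) {
  miss <- setdiff(control_sample_ids, rownames(table))
  if (length(miss))
    stop("control sample(s) not in table: ", paste(miss, collapse = ", "))
  ctrl <- table[control_sample_ids, , drop = FALSE]
  removed <- colnames(table)[colSums(ctrl > 0) > 0]
  keep_rows <- setdiff(rownames(table), control_sample_ids)
  keep_cols <- setdiff(colnames(table), removed)
  out <- table[keep_rows, keep_cols, drop = FALSE]
  at <- attributes(table)
  attr(out, "rank") <- at$rank; attr(out, "threshold") <- at$threshold
  if (!is.null(at$taxa))
    attr(out, "taxa") <- at$taxa[at$taxa$taxon %in% keep_cols, , drop = FALSE]
  class(out) <- class(table)
  list(table = out, removed_taxa = removed)
}

#' Percent increase of site-level over sample-level mean richness
#' @param mean_per_sample,mean_per_site mean species richness per indexed
#'   sample and per site.
#' @return percentage increase (not rounded).
#' @export
richness_gain_pct <- function(mean_per_sample, mean_per_site) {
  100 * (mean_per_site - mean_per_sample) / mean_per_sample
}

#' Replicate-aware detection statistics
#'
#' Richness per indexed sample is the number of taxa with a nonzero count;
#' per-site richness is the richness of the union over that site's
#' replicates. The gain from replication is decomposed by counting, per
#' site, the richness reached by the union of each field replicate's first
#' amplification (RPA) replicate (field-replication gain over the mean
#' single sample) and the remainder up to the full site union
#' (RPA-replication gain); the two are normalised to percentages of the
#' total gain.
#'
#' @param table a post-filter species-rank `taxon_count_table`.
#' @param sheet a [sample_sheet].
#' @return list with `mean_species_per_indexed_sample`,
#'   `mean_species_per_site`, `pct_increase` (rounded to integer),
#'   `attribution_field_pct`, `attribution_rpa_pct`, and the per-site
#'   breakdown `sites`.
#' @export
detection_stats <- function(table, sheet) {
  meta <- sheet[match(rownames(table), sheet$sample_id), ]
  use <- !meta$is_negative_control & meta$marker == "edna"
  tab <- table[use, , drop = FALSE]
  meta <- meta[use, ]
  rich <- rowSums(tab > 0)
  sites <- unique(meta$site_id)
  per_site <- lapply(sites, function(s) {
    rows <- which(meta$site_id == s)
    if (length(rows) == 0) return(NULL)
    sub <- tab[rows, , drop = FALSE]
    union_rich <- sum(colSums(sub > 0) > 0)
    first_rpa <- rows[meta$rpa_replicate[rows] == min(meta$rpa_replicate[rows])]
    u_first <- sum(colSums(tab[first_rpa, , drop = FALSE] > 0) > 0)
    mean_single <- mean(rich[rows])
    list(site = s, mean_single = mean_single, union = union_rich,
         gain_field = max(0, u_first - mean_single),
         gain_rpa = max(0, union_rich - u_first))
  })
  per_site <- Filter(Negate(is.null), per_site)
  mean_sample <- mean(rich)
  mean_site <- mean(vapply(per_site, `[[`, 0, "union"))
  gf <- sum(vapply(per_site, `[[`, 0, "gain_field"))
  gr <- sum(vapply(per_site, `[[`, 0, "gain_rpa"))
  tot <- gf + gr
  list(mean_species_per_indexed_sample = mean_sample,
       mean_species_per_site = mean_site,
       pct_increase = round(richness_gain_pct(mean_sample, mean_site)),
       attribution_field_pct = if (tot > 0) 100 * gf / tot else NA_real_,
       attribution_rpa_pct = if (tot > 0) 100 * gr / tot else NA_real_,
       sites = per_site)
}

#' Elevational summary of read counts
#'
#' Sites are binned into elevational cohorts by `bin_edges` (left-closed,
#' right-open; the last bin closed). For each species and cohort the mean
#' read count across ALL replicate samples in the cohort (zeros included)
#' is reported on the natural-log scale; a mean of zero is reported as
#' absent (`NA`), which is distinct from `ln(1) = 0`.
#'
#' @param table a post-filter species-rank `taxon_count_table`.
#' @param sheet a [sample_sheet].
#' @param bin_edges strictly increasing numeric vector of cohort edges.
#' @return data.frame species x cohort with `ln_mean_count` (NA = absent).
#' @export
elevational_summary <- function(table, sheet, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  meta <- sheet[match(rownames(table), sheet$sample_id), ]
  use <- !meta$is_negative_control & meta$marker == "edna"
  tab <- table[use, , drop = FALSE]
  meta <- meta[use, ]
  cohort <- cut(meta$elevation_m, bin_edges, right = FALSE,
                include.lowest = TRUE)
  out <- list()
  for (co in levels(cohort)) {
    rows <- which(cohort == co)
    if (length(rows) == 0) next
    mu <- colMeans(tab[rows, , drop = FALSE])
    out[[co]] <- data.frame(cohort = co, species = colnames(tab),
                            mean_count = mu,
                            ln_mean_count = ifelse(mu > 0, log(mu), NA_real_),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
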