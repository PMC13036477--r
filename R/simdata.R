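# Nanopore-like amplicon read simulator. The stated world: a nested marker
# design (a ~250 bp eDNA amplicon sitting inside a ~600 bp barcoding
# amplicon, sharing conserved primer sites), dual 20-base indexes on both
# ends, i.i.d. per-base substitution/insertion/deletion errors with quality
# strings, log-normally skewed community abundances, terrestrial taxa
# down-weighted in water samples, non-target "bycatch" taxa that amplify
# with the same primers, and a negative control carrying trace
# contamination.

#' Per-base sequencing error model
#'
#' Independent per-base error process: each template base is substituted
#' with probability `p_sub`, deleted with `p_del`, and followed by an
#' inserted base with probability `p_ins`. Qualities are drawn around
#' `quality_correct` for faithful bases and `quality_error` for erroneous
#' ones. Defaults approximate modern Nanopore chemistry after accurate
#' basecalling (a few percent total error).
#'
#' @param p_sub,p_ins,p_del per-base error probabilities; their sum must be
#'   below 1. Defaults total 1 percent, the raw-read accuracy (~Q20) of
#'   current flow cells under accurate basecalling.
#' @param quality_correct,quality_error mean Phred scores for correct and
#'   erroneous bases.
#' @return list of class `error_model`.
#' @export
error_model <- function(p_sub = 0.005, p_ins = 0.0025, p_del = 0.0025,
                        quality_correct = 20, quality_error = 8) {
  stopifnot(p_sub >= 0, p_ins >= 0, p_del >= 0, p_sub + p_ins + p_del < 1)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 quality_correct = quality_correct,
                 quality_error = quality_error),
            class = "error_model")
}

DNA_BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# substitute each mutable position with probability p (uniform other base)
mutate_seq <- function(seq, p, mutable) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < p & mutable
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(DNA_BASES, b), 1), "")
  }
  paste(ch, collapse = "")
}

# amplicon geometry on a template of length seq_len: the barcoding amplicon
# spans the whole template, the eDNA amplicon is nested inside it; each has
# 28-base primer sites kept free of mutations (conserved).
marker_layout <- function(seq_len, primer_len = 28L, edna_amplicon = 250L) {
  s <- (seq_len - edna_amplicon) %/% 2 + 1L
  list(primer_len = primer_len,
       barcode = c(1L, seq_len),
       edna = c(s, s + edna_amplicon - 1L),
       barcode_insert = c(primer_len + 1L, seq_len - primer_len),
       edna_insert = c(s + primer_len, s + edna_amplicon - 1L - primer_len))
}

#' Simulate a reference community along a random phylogeny
#'
#' Sequences descend from a random ancestor along a random bifurcating tree
#' whose branch lengths are rescaled so the mean pairwise distance between
#' genera is approximately `divergence`. Roughly one third of taxa get a
#' congeneric sister species at about one quarter of the between-genus
#' divergence, so species-level and genus-level assignment differ
#' meaningfully. Primer binding sites (28 bases at both ends of both the
#' long and the nested marker) are conserved across all taxa, including
#' bycatch. For every local taxon a non-local congeneric "relative" (not on
#' any checklist) is also produced: these stand in for the related but
#' extralimital sequences a public database contains.
#'
#' @param n_taxa number of local (target-class) taxa, at least 2.
#' @param seq_len template length in bases (default 600; must fit the
#'   nested 250-base marker).
#' @param divergence target mean pairwise distance between genera in
#'   substitutions per mutable site (primer binding sites are conserved and
#'   excluded), in \[0, 0.5). Multiple hits shrink observed distances a few
#'   percent below the nominal value at 0.1.
#' @param n_bycatch number of non-target taxa that co-amplify.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_community` with elements `taxa`
#'   (data.frame incl. `seq_long`, `seq_short`), `relatives`, `primers`,
#'   `layout` and `seed`.
#' @export
simulate_references <- function(n_taxa, seq_len = 600L, divergence = 0.10,
                                n_bycatch = 3L, seed = 1L) {
  stopifnot(n_taxa >= 2, divergence >= 0, divergence < 0.5)
  if (seq_len < 250L)
    stop("seq_len must be at least 250 to hold the nested short marker")
  set.seed(seed)
  lay <- marker_layout(seq_len)
  mutable <- rep(TRUE, seq_len)
  for (iv in list(c(1L, lay$primer_len),
                  c(seq_len - lay$primer_len + 1L, seq_len),
                  c(lay$edna[1], lay$edna[1] + lay$primer_len - 1L),
                  c(lay$edna[2] - lay$primer_len + 1L, lay$edna[2])))
    mutable[iv[1]:iv[2]] <- FALSE

  n_paired <- if (n_taxa >= 3) floor(n_taxa / 3) else 0L
  n_genera <- n_taxa - n_paired
  ancestor <- random_seq(seq_len)

  # genus representatives evolve along a random bifurcating tree carrying
  # half the target divergence, plus a private stem (divergence/4 per tip)
  # so no two genera sit closer than ~divergence/2 — keeping between-genus
  # distances clear of the congeneric level (divergence/4)
  reps <- character(n_genera)
  if (n_genera == 1L || divergence == 0) {
    for (i in seq_len(n_genera))
      reps[i] <- if (divergence == 0) ancestor else
        mutate_seq(ancestor, divergence / 2, mutable)
  } else {
    tr <- ape::rtree(n_genera)
    d <- ape::cophenetic.phylo(tr)
    scale <- (divergence / 2) / mean(d[upper.tri(d)])
    tr$edge.length <- tr$edge.length * scale
    nnode <- max(tr$edge)
    seqs <- vector("list", nnode)
    root <- n_genera + 1L
    seqs[[root]] <- ancestor
    ord <- order(tr$edge[, 1])  # parents before children in rtree numbering
    for (e in ord) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      seqs[[child]] <- mutate_seq(seqs[[par]], tr$edge.length[e], mutable)
    }
    reps <- unlist(seqs[seq_len(n_genera)])[order(as.integer(sub("t", "", tr$tip.label)))]
    reps <- vapply(reps, function(s) mutate_seq(s, divergence / 4, mutable), "",
                   USE.NAMES = FALSE)
  }

  genus_names <- sprintf("Genus%02d", seq_len(n_genera))
  taxa <- data.frame(species_name = paste(genus_names, "primus"),
                     genus_name = genus_names,
                     seq_long = reps, stringsAsFactors = FALSE)
  if (n_paired > 0) {
    sib <- data.frame(
      species_name = paste(genus_names[seq_len(n_paired)], "secundus"),
      genus_name = genus_names[seq_len(n_paired)],
      seq_long = vapply(reps[seq_len(n_paired)],
                        function(s) mutate_seq(s, divergence / 4, mutable), "",
                        USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    taxa <- rbind(taxa, sib)
  }
  taxa <- taxa[seq_len(n_taxa), ]
  taxa$class <- "Amphibia"
  taxa$order <- "Anura"
  taxa$family <- "Simufamilia"
  taxa$is_bycatch <- FALSE
  taxa$life_history <- sample(c("aquatic", "terrestrial"), n_taxa, replace = TRUE)
  ctr <- runif(n_taxa, 200, 2800)
  half <- runif(n_taxa, 500, 1200)
  taxa$elev_lo <- pmax(0, round(ctr - half))
  taxa$elev_hi <- round(ctr + half)
  ab <- rlnorm(n_taxa, 0, 1.5)
  taxa$abundance <- ab / sum(ab)

  if (n_bycatch > 0) {
    by_class <- rep(c("Mammalia", "Actinopteri", "Aves"), length.out = n_bycatch)
    byc <- data.frame(
      species_name = sprintf("Bycatus%02d incidentalis", seq_len(n_bycatch)),
      genus_name = sprintf("Bycatus%02d", seq_len(n_bycatch)),
      seq_long = vapply(seq_len(n_bycatch),
                        function(i) mutate_seq(ancestor, 0.35, mutable), ""),
      class = by_class, order = "Varia", family = "Variidae",
      is_bycatch = TRUE,
      life_history = "aquatic",
      elev_lo = 0L, elev_hi = 4000L,
      abundance = NA_real_, stringsAsFactors = FALSE)
    ab2 <- rlnorm(n_bycatch, -1, 1)      # bycatch rarer than targets
    byc$abundance <- ab2 / sum(ab2) * 0.15
    taxa$abundance <- taxa$abundance * 0.85
    taxa <- rbind(taxa, byc)
  }
  taxa$seq_short <- substr(taxa$seq_long, lay$edna[1], lay$edna[2])

  relatives <- data.frame(
    species_name = paste(taxa$genus_name[!taxa$is_bycatch], "extraneus"),
    genus_name = taxa$genus_name[!taxa$is_bycatch],
    class = "Amphibia", order = "Anura", family = "Simufamilia",
    seq_long = vapply(taxa$seq_long[!taxa$is_bycatch],
                      function(s) mutate_seq(s, divergence / 4, mutable), "",
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  site <- function(iv) substr(ancestor, iv[1], iv[2])
  primers <- list(
    edna = c(f = site(c(lay$edna[1], lay$edna[1] + lay$primer_len - 1L)),
             r = revcomp(site(c(lay$edna[2] - lay$primer_len + 1L, lay$edna[2])))),
    barcode = c(f = site(c(1L, lay$primer_len)),
                r = revcomp(site(c(seq_len - lay$primer_len + 1L, seq_len)))))

  structure(list(taxa = taxa, relatives = relatives, primers = primers,
                 layout = lay, ancestor = ancestor, seed = seed),
            class = "synthetic_community")
}

#' Default sample sheet for simulated runs
#'
#' eDNA samples cover `n_sites` sites spread over an elevational gradient,
#' with `field_reps` field replicates x `rpa_reps` amplification (RPA)
#' replicates each, plus one negative control; barcoding samples are
#' single-specimen swabs. Dual 20-base indexes are drawn at random,
#' distinct across samples.
#'
#' @param n_sites number of eDNA field sites.
#' @param field_reps,rpa_reps replicates per site and per field replicate.
#' @param n_specimens number of single-specimen barcoding samples.
#' @param elev_range elevational span covered by the sites (metres).
#' @param seed integer RNG seed.
#' @return a validated [sample_sheet].
#' @export
simulate_sample_sheet <- function(n_sites = 13L, field_reps = 2L, rpa_reps = 2L,
                                  n_specimens = 0L, elev_range = c(200, 3000),
                                  seed = 1L) {
  set.seed(seed)
  n_edna <- n_sites * field_reps * rpa_reps
  n <- n_edna + n_specimens + 1L  # + negative control
  idx_f <- idx_r <- character(n)
  repeat {
    idx_f <- vapply(seq_len(n), function(i) random_seq(20L), "")
    idx_r <- vapply(seq_len(n), function(i) random_seq(20L), "")
    if (!anyDuplicated(paste(idx_f, idx_r))) break
  }
  elev <- round(seq(elev_range[1], elev_range[2], length.out = n_sites))
  grid <- expand.grid(rpa = seq_len(rpa_reps), fld = seq_len(field_reps),
                      site = seq_len(n_sites))
  rows <- data.frame(
    sample_id = sprintf("S%02d_F%d_R%d", grid$site, grid$fld, grid$rpa),
    index_f = idx_f[seq_len(n_edna)], index_r = idx_r[seq_len(n_edna)],
    marker = "edna",
    site_id = sprintf("site%02d", grid$site),
    elevation_m = elev[grid$site],
    field_replicate = grid$fld, rpa_replicate = grid$rpa,
    is_negative_control = FALSE, stringsAsFactors = FALSE)
  if (n_specimens > 0) {
    k <- n_edna + seq_len(n_specimens)
    rows <- rbind(rows, data.frame(
      sample_id = sprintf("SPEC%02d", seq_len(n_specimens)),
      index_f = idx_f[k], index_r = idx_r[k],
      marker = "barcode",
      site_id = sprintf("site%02d", sample.int(n_sites, n_specimens, replace = TRUE)),
      elevation_m = sample(elev, n_specimens, replace = TRUE),
      field_replicate = 1L, rpa_replicate = 1L,
      is_negative_control = FALSE, stringsAsFactors = FALSE))
  }
  rows <- rbind(rows, data.frame(
    sample_id = "NEG01", index_f = idx_f[n], index_r = idx_r[n],
    marker = "edna", site_id = "control", elevation_m = 0L,
    field_replicate = 1L, rpa_replicate = 1L,
    is_negative_control = TRUE, stringsAsFactors = FALSE))
  sample_sheet(rows)
}

# apply the i.i.d. error process to one sequence; returns list(seq, qual)
apply_errors <- function(seq, model) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  qual <- as.integer(pmax(2, pmin(40, round(rnorm(n, model$quality_correct, 3)))))
  u <- runif(n)
  is_sub <- u < model$p_sub
  is_del <- !is_sub & u < model$p_sub + model$p_del
  is_ins <- !is_sub & !is_del & u < model$p_sub + model$p_del + model$p_ins
  if (any(is_sub)) {
    ch[is_sub] <- vapply(ch[is_sub], function(b) sample(setdiff(DNA_BASES, b), 1), "")
    qual[is_sub] <- as.integer(pmax(2, pmin(40, round(rnorm(sum(is_sub), model$quality_error, 2)))))
  }
  keep <- which(!is_del)
  ins_at <- which(is_ins)
  pos <- c(keep, ins_at + 0.5)
  ord <- order(pos)
  ins_q <- as.integer(pmax(2, pmin(40, round(rnorm(length(ins_at), model$quality_error, 2)))))
  out_ch <- c(ch[keep], sample(DNA_BASES, length(ins_at), replace = TRUE))[ord]
  out_q <- c(qual[keep], ins_q)[ord]
  list(seq = paste(out_ch, collapse = ""), qual = out_q)
}

#' Simulate pooled dual-indexed amplicon reads
#'
#' Each read is built as `index_f + forward primer site + marker insert +
#' reverse primer site + revcomp(index_r)` on the forward strand, the error
#' process of `model` is applied to every base, and about half of the reads
#' are emitted reverse-complemented, as in a real pooled sequencing run.
#' eDNA samples draw taxa whose elevational range contains the sample's
#' elevation, weighted by abundance with terrestrial taxa down-weighted by
#' `terrestrial_factor`; single-specimen barcoding samples draw all their
#' reads from one taxon (the swabbed specimen). The negative control
#' receives `contamination_frac * reads_per_sample` contaminating reads
#' from arbitrary taxa.
#'
#' @param community a [simulate_references] result.
#' @param sheet a [sample_sheet].
#' @param model an [error_model].
#' @param reads_per_sample reads drawn per non-control sample (> 0).
#' @param seed integer RNG seed.
#' @param contamination_frac fraction of `reads_per_sample` given to each
#'   negative control (default 0.5 percent).
#' @param terrestrial_factor eDNA detectability multiplier for terrestrial
#'   taxa (default 0.05).
#' @param specimen_taxa optional named character vector mapping barcoding
#'   sample ids to species names (the field identification of each swabbed
#'   specimen); unmapped specimens draw a random eligible taxon.
#' @return list with `reads` (a pooled, shuffled [seq_records]) and `truth`
#'   (data.frame read_id, sample_id, species_name, marker).
#' @export
simulate_reads <- function(community, sheet, model = error_model(),
                           reads_per_sample = 200L, seed = 1L,
                           contamination_frac = 0.005,
                           terrestrial_factor = 0.05,
                           specimen_taxa = NULL) {
  if (reads_per_sample <= 0) stop("reads_per_sample must be positive")
  stopifnot(inherits(community, "synthetic_community"))
  set.seed(seed)
  lay <- community$layout
  taxa <- community$taxa
  per_sample <- vector("list", nrow(sheet))
  counter <- 0L
  for (r in seq_len(nrow(sheet))) {
    row <- sheet[r, ]
    n_reads <- if (row$is_negative_control)
      round(contamination_frac * reads_per_sample) else reads_per_sample
    if (n_reads == 0) next
    if (row$is_negative_control) {
      w <- rep(1, nrow(taxa))
    } else {
      elig <- taxa$elev_lo <= row$elevation_m & taxa$elev_hi >= row$elevation_m
      w <- taxa$abundance * elig
      if (row$marker == "edna")
        w <- w * ifelse(taxa$life_history == "terrestrial", terrestrial_factor, 1)
      if (sum(w) == 0) {
        warning("no eligible taxa for sample ", row$sample_id, "; emitting none")
        next
      }
    }
    pick <- if (row$marker == "barcode" && !row$is_negative_control) {
      tx <- if (!is.null(specimen_taxa) && row$sample_id %in% names(specimen_taxa))
        match(specimen_taxa[[row$sample_id]], taxa$species_name)
      else sample.int(nrow(taxa), 1L, prob = w)
      if (is.na(tx)) stop("unknown specimen species for ", row$sample_id)
      rep(tx, n_reads)  # one specimen per swab
    } else {
      sample.int(nrow(taxa), n_reads, replace = TRUE, prob = w)
    }
    iv <- if (row$marker == "edna") lay$edna_insert else lay$barcode_insert
    pf <- community$primers[[row$marker]]["f"]
    pr_site <- revcomp(community$primers[[row$marker]]["r"])
    tpl <- paste0(row$index_f, pf, substr(taxa$seq_long[pick], iv[1], iv[2]),
                  pr_site, revcomp(row$index_r))
    seqs <- character(n_reads); quals <- vector("list", n_reads)
    flip <- runif(n_reads) < 0.5
    for (k in seq_len(n_reads)) {
      rd <- apply_errors(tpl[k], model)
      if (flip[k]) {
        rd$seq <- revcomp(rd$seq)
        rd$qual <- rev(rd$qual)
      }
      seqs[k] <- rd$seq; quals[[k]] <- rd$qual
    }
    per_sample[[r]] <- list(
      ids = sprintf("read%06d", counter + seq_len(n_reads)),
      seqs = seqs, quals = quals,
      truth = data.frame(read_id = sprintf("read%06d", counter + seq_len(n_reads)),
                         sample_id = row$sample_id,
                         species_name = taxa$species_name[pick],
                         marker = row$marker, stringsAsFactors = FALSE))
    counter <- counter + n_reads
  }
  per_sample <- Filter(Negate(is.null), per_sample)
  ids <- unlist(lapply(per_sample, `[[`, "ids"))
  seqs <- unlist(lapply(per_sample, `[[`, "seqs"))
  quals <- do.call(c, lapply(per_sample, `[[`, "quals"))
  truth <- do.call(rbind, lapply(per_sample, `[[`, "truth"))
  ord <- sample.int(length(ids))  # pool: shuffle as a run would
  list(reads = seq_records(ids[ord], seqs[ord], quals[ord]),
       truth = truth)
}
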