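# Shared fixtures and independent oracles, kept deliberately separate from
# the package's own algorithms.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# full-matrix Levenshtein distance (no banding) — oracle for edit_distance
lv_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b))
    d[i + 1, j + 1] <- min(d[i, j] + (a[i] != b[j]), d[i, j + 1] + 1L,
                           d[i + 1, j] + 1L)
  d[length(a) + 1, length(b) + 1]
}

# full-matrix affine-gap Smith-Waterman score (Gotoh, three matrices) —
# oracle for align_identity's local score; match +2, mismatch -3, gap of
# length L costs 5 + 2L
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e18
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1); F <- E
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, E[i, j + 1] - ext)
    F[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, F[i + 1, j] - ext)
    s <- if (a[i] == b[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# plant k substitutions at distinct positions
mutate_k <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# small community + sheet + reads, shared across demux/consensus tests
small_sim <- function(n_taxa = 6, n_sites = 2, n_specimens = 1,
                      reads_per_sample = 30, model = error_model(),
                      seed = 11) {
  com <- simulate_references(n_taxa, divergence = 0.10, seed = seed)
  sheet <- simulate_sample_sheet(n_sites = n_sites, field_reps = 2,
                                 rpa_reps = 1, n_specimens = n_specimens,
                                 seed = seed + 1)
  sim <- simulate_reads(com, sheet, model, reads_per_sample, seed = seed + 2)
  list(com = com, sheet = sheet, sim = sim)
}

# one desk-scale end-to-end run shared across test files (the stated world
# of 13 sites and thousands of reads per sample is scaled down for speed;
# these tests check structure, not size)
run_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        run_all(run_config(rng_seed = 7), n_taxa = 9, n_sites = 4,
                field_reps = 2, rpa_reps = 2, n_specimens = 9,
                reads_per_sample = 40))
    cache
  }
})

# hand-built hit tables: three samples (one a negative control), known sizes
toy_hits <- function() {
  mk <- function(qn, size, species, genus, class = "Amphibia",
                 p95 = TRUE, p99 = FALSE) {
    data.frame(query_id = qn, size = size, accession = paste0("GB", qn),
               percent_identity = 96, alignment_length = 190, score = 300,
               kingdom = "Metazoa", phylum = "Chordata", class = class,
               order = "Anura", family = "F", genus = genus, species = species,
               provenance = "base", pass95 = p95, pass99 = p99,
               stringsAsFactors = FALSE)
  }
  list(
    s1 = rbind(mk("q1", 7, "X a", "X"), mk("q2", 4, "X a", "X"),
               mk("q3", 9, "Y b", "Y", p99 = TRUE)),
    s2 = rbind(mk("q4", 3, "X a", "X"), mk("q5", 12, "Z c", "Z")),
    neg = mk("q6", 12, "Z c", "Z"))
}

toy_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("s1", "s2", "neg"),
    index_f = c(strrep("A", 20), strrep("C", 20), strrep("G", 20)),
    index_r = c(strrep("T", 20), strrep("G", 20), strrep("A", 20)),
    marker = "edna", site_id = c("site1", "site1", "control"),
    elevation_m = c(100, 100, 0), field_replicate = c(1, 2, 1),
    rpa_replicate = 1, is_negative_control = c(FALSE, FALSE, TRUE)))
}

# minimal reference db: local taxa + relatives + bycatch from a community
community_db <- function(com, include_species = NULL) {
  taxa <- com$taxa
  keep <- is.null(include_species) | taxa$species_name %in%
    c(include_species, taxa$species_name[taxa$is_bycatch])
  rows <- rbind(
    data.frame(species = taxa$species_name[keep], genus = taxa$genus_name[keep],
               class = taxa$class[keep], seq = taxa$seq_long[keep]),
    data.frame(species = com$relatives$species_name,
               genus = com$relatives$genus_name,
               class = com$relatives$class, seq = com$relatives$seq_long))
  lin <- data.frame(kingdom = "Metazoa", phylum = "Chordata",
                    class = rows$class, order = "UNKNOWN", family = "UNKNOWN",
                    genus = rows$genus, species = rows$species)
  reference_db(sprintf("GB%05d", seq_len(nrow(rows))), lin, rows$seq)
}
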