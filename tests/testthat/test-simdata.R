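test_that("reference simulation hits its divergence target (brute-force oracle)", {
  com <- simulate_references(20, divergence = 0.10, seed = 7)
  tx <- com$taxa[!com$taxa$is_bycatch, ]
  lay <- com$layout
  # mutable columns: everything outside the four conserved primer sites
  mut <- rep(TRUE, nchar(com$ancestor))
  p <- lay$primer_len
  for (iv in list(c(1, p), c(nchar(com$ancestor) - p + 1, nchar(com$ancestor)),
                  c(lay$edna[1], lay$edna[1] + p - 1),
                  c(lay$edna[2] - p + 1, lay$edna[2])))
    mut[iv[1]:iv[2]] <- FALSE
  ham <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x[mut] != y[mut])
  }
  n <- nrow(tx)
  d <- c(); same_genus <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- c(d, ham(tx$seq_long[i], tx$seq_long[j]))
    same_genus <- c(same_genus, tx$genus_name[i] == tx$genus_name[j])
  }
  expect_gt(mean(d), 0.08)  # within +/- 20% of the 0.10 target
  expect_lt(mean(d), 0.12)
  # congeneric pairs sit well below between-genus divergence
  expect_lt(mean(d[same_genus]), 0.5 * mean(d[!same_genus]))
})

test_that("degenerate and deterministic limits of the reference simulator", {
  com0 <- simulate_references(4, divergence = 0, seed = 3)
  tx <- com0$taxa[!com0$taxa$is_bycatch, ]
  expect_true(all(tx$seq_long == tx$seq_long[1]))
  a <- simulate_references(8, divergence = 0.10, seed = 5)
  b <- simulate_references(8, divergence = 0.10, seed = 5)
  expect_identical(a$taxa$seq_long, b$taxa$seq_long)
  expect_error(simulate_references(4, seq_len = 200, seed = 1), "nested")
  # nesting: short marker is a substring of the long sequence
  com <- simulate_references(6, seed = 9)
  expect_true(all(mapply(grepl, com$taxa$seq_short, com$taxa$seq_long,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("substitution counts match the binomial oracle on the truth table", {
  com <- simulate_references(4, divergence = 0.05, seed = 21)
  sheet <- simulate_sample_sheet(n_sites = 1, field_reps = 1, rpa_reps = 1,
                                 seed = 22)
  model <- error_model(p_sub = 0.05, p_ins = 0, p_del = 0,
                       quality_correct = 20, quality_error = 8)
  sim <- simulate_reads(com, sheet, model, reads_per_sample = 40, seed = 23)
  # with no indels, each read aligns column-to-column to its template
  truth <- sim$truth
  lay <- com$layout
  row <- sheet[!sheet$is_negative_control, ][1, ]
  nsub <- 0; nbase <- 0
  for (i in seq_len(nrow(sim$reads))) {
    tr <- truth[truth$read_id == sim$reads$id[i], ]
    if (tr$sample_id != row$sample_id) next
    tx <- match(tr$species_name, com$taxa$species_name)
    iv <- lay$edna_insert
    tpl <- paste0(row$index_f, com$primers$edna["f"],
                  substr(com$taxa$seq_long[tx], iv[1], iv[2]),
                  revcomp(com$primers$edna["r"]), revcomp(row$index_r))
    rd <- sim$reads$seq[i]
    if (!nchar(rd) == nchar(tpl)) next
    fw <- sum(strsplit(rd, "")[[1]] != strsplit(tpl, "")[[1]])
    rv <- sum(strsplit(revcomp(rd), "")[[1]] != strsplit(tpl, "")[[1]])
    nsub <- nsub + min(fw, rv)
    nbase <- nbase + nchar(tpl)
  }
  expect_gt(nbase, 10000)
  ci <- qbinom(c(0.005, 0.995), nbase, 0.05)
  expect_gte(nsub, ci[1])
  expect_lte(nsub, ci[2])
})

test_that("read pools conserve counts, cover the truth table, and are seeded", {
  s <- small_sim(reads_per_sample = 25)
  sheet <- s$sheet
  n_expect <- 25 * sum(!sheet$is_negative_control) +
    round(0.005 * 25) * sum(sheet$is_negative_control)
  expect_equal(nrow(s$sim$reads), n_expect)
  expect_setequal(s$sim$truth$read_id, s$sim$reads$id)
  expect_equal(anyDuplicated(s$sim$truth$read_id), 0L)
  again <- simulate_reads(s$com, sheet, error_model(), 25, seed = 13)
  expect_identical(again$reads$seq, s$sim$reads$seq)
  expect_error(simulate_reads(s$com, sheet, error_model(), 0), "positive")
})

test_that("zero-error reads reproduce their templates exactly", {
  com <- simulate_references(4, divergence = 0.08, seed = 31)
  sheet <- simulate_sample_sheet(n_sites = 1, field_reps = 1, rpa_reps = 1,
                                 seed = 32)
  model <- error_model(0, 0, 0)
  sim <- simulate_reads(com, sheet, model, reads_per_sample = 10, seed = 33)
  lay <- com$layout
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[sim$truth$read_id == sim$reads$id[i], ]
    if (tr$sample_id == "NEG01") next
    tx <- match(tr$species_name, com$taxa$species_name)
    iv <- lay$edna_insert
    marker <- substr(com$taxa$seq_long[tx], iv[1], iv[2])
    hit <- grepl(marker, sim$reads$seq[i], fixed = TRUE) ||
      grepl(marker, revcomp(sim$reads$seq[i]), fixed = TRUE)
    expect_true(hit)
  }
})
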