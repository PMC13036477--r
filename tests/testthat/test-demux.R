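test_that("edit distance equals the full-DP oracle whenever within the cap", {
  set.seed(101)
  for (k in 1:60) {
    a <- rand_seq(sample(15:25, 1))
    b <- if (k %% 3 == 0) mutate_k(a, sample(1:3, 1)) else rand_seq(sample(15:25, 1))
    cap <- sample(1:4, 1)
    truth <- lv_oracle(a, b)
    got <- edit_distance(a, b, cap)
    if (truth <= cap) expect_equal(got, truth) else expect_equal(got, cap + 1L)
  }
  expect_equal(edit_distance("ACGT", "ACGT", 2), 0L)
  expect_equal(edit_distance("AAAA", "TTTT", 2), 3L)  # sentinel cap + 1
  a20 <- strrep("ACGT", 5)
  expect_equal(edit_distance(a20, mutate_k(a20, 2, seed = 1), 2), 2L)
})

test_that("reads are assigned to their truth sample within tolerance, tie rule holds", {
  s <- small_sim(reads_per_sample = 25, model = error_model(0.02, 0.01, 0.01))
  dm <- demultiplex(s$sim$reads, s$sheet, 2, 3, s$com$primers)
  r <- dm$results
  # partition: every read appears exactly once
  expect_setequal(r$read_id, s$sim$reads$id)
  truth_sample <- s$sim$truth$sample_id[match(r$read_id, s$sim$truth$read_id)]
  ok <- !is.na(r$sample_id)
  expect_gt(mean(ok), 0.8)
  expect_equal(sum(r$sample_id[ok] != truth_sample[ok]), 0)
  # summary accounts for all reads
  expect_equal(sum(dm$summary$n_reads), nrow(s$sim$reads))
  expect_error(demultiplex(s$sim$reads, s$sheet[0, ], 2, 3), "empty")
})

test_that("index errors are tolerated up to tol and no further", {
  sheet <- simulate_sample_sheet(n_sites = 1, field_reps = 1, rpa_reps = 1,
                                 seed = 41)
  row <- sheet[1, ]
  insert <- rand_seq(190)
  read <- paste0(mutate_k(row$index_f, 2, seed = 42), insert,
                 revcomp(row$index_r))
  reads <- seq_records("q1", read)
  hit2 <- demultiplex(reads, sheet, tol_index = 2)$results
  expect_equal(hit2$sample_id, row$sample_id)
  hit1 <- demultiplex(reads, sheet, tol_index = 1)$results
  expect_true(is.na(hit1$sample_id))
  expect_equal(hit1$reason, "no_match")
})

test_that("ties between two samples are left ambiguous, never assigned", {
  idx <- replicate(4, rand_seq(20))
  sheet <- sample_sheet(data.frame(
    sample_id = c("s1", "s2"), index_f = idx[1], index_r = c(idx[2], idx[3]),
    marker = "edna", site_id = "x", elevation_m = 0,
    field_replicate = 1, rpa_replicate = 1, is_negative_control = FALSE))
  # reverse index differs between samples; give the read a third sequence
  # equidistant (1 edit) from both samples' index_r
  ir1 <- strsplit(idx[2], "")[[1]]; ir2 <- ir1
  ir1[5] <- setdiff(c("A", "C", "G", "T"), ir1[5])[1]
  ir2[9] <- setdiff(c("A", "C", "G", "T"), ir2[9])[1]
  sheet$index_r <- c(paste(ir1, collapse = ""), paste(ir2, collapse = ""))
  read <- paste0(idx[1], rand_seq(190), revcomp(idx[2]))
  res <- demultiplex(seq_records("q", read), sheet, tol_index = 2)$results
  expect_true(is.na(res$sample_id))
  expect_equal(res$reason, "ambiguous")
})

test_that("raising the index tolerance never decreases the assigned count", {
  set.seed(51)
  s <- small_sim(reads_per_sample = 20, model = error_model(0.05, 0.02, 0.02))
  counts <- vapply(0:3, function(tol) {
    sum(!is.na(demultiplex(s$sim$reads, s$sheet, tol)$results$sample_id))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("inserts are primer-trimmed to the marker and reported forward-sense", {
  com <- simulate_references(4, divergence = 0.08, seed = 61)
  sheet <- simulate_sample_sheet(n_sites = 1, field_reps = 1, rpa_reps = 1,
                                 seed = 62)
  sim <- simulate_reads(com, sheet, error_model(0, 0, 0), 20, seed = 63)
  dm <- demultiplex(sim$reads, sheet, 2, 3, com$primers)
  r <- dm$results[!is.na(dm$results$sample_id) & dm$results$primer_trimmed, ]
  expect_gt(nrow(r), 15)
  iv <- com$layout$edna_insert
  markers <- substr(com$taxa$seq_long, iv[1], iv[2])
  expect_true(all(r$insert %in% markers))  # exact template recovery, forward
  # quality travels with the trimmed insert
  expect_true(all(vapply(seq_len(nrow(r)),
                         function(i) length(r$qual[[i]]) == nchar(r$insert[i]),
                         TRUE)))
})
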