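test_that("tabulation sums sizes per taxon and respects thresholds", {
  tab <- tabulate_hits(toy_hits(), toy_sheet(), "species", 95)
  expect_equal(tab["s1", "X a"], 11L)   # 7 + 4
  expect_equal(tab["s1", "Y b"], 9L)
  expect_equal(tab["s2", "Z c"], 12L)
  t99 <- tabulate_hits(toy_hits(), toy_sheet(), "species", 99)
  expect_equal(t99["s1", "Y b"], 9L)
  expect_false("X a" %in% colnames(t99))  # fails 99 everywhere
  expect_equal(sum(tab), 7L + 4L + 9L + 3L + 12L + 12L)
  bad <- toy_hits(); names(bad)[1] <- "ghost"
  expect_error(tabulate_hits(bad, toy_sheet(), "species", 95), "ghost")
})

test_that("noise floor zeroes cells at or below 5 and nothing else", {
  tab <- tabulate_hits(toy_hits(), toy_sheet(), "species", 95)
  fl <- apply_noise_floor(tab, 5)
  expect_equal(fl["s2", "X a"], 0L)    # 3 <= 5 -> 0
  expect_equal(fl["s1", "X a"], 11L)
  m <- matrix(c(5L, 6L, 0L), 1, dimnames = list("s", c("a", "b", "c")))
  fm <- apply_noise_floor(m)
  expect_equal(unname(fm[1, ]), c(0L, 6L, 0L))
})

test_that("control-taxon removal follows the documented order of operations", {
  tab <- tabulate_hits(toy_hits(), toy_sheet(), "species", 95)
  fl <- apply_noise_floor(tab, 5)
  out <- remove_control_taxa(fl, "neg")
  # Z c has 12 reads in the control -> removed everywhere, control dropped
  expect_equal(out$removed_taxa, "Z c")
  expect_false("Z c" %in% colnames(out$table))
  expect_false("neg" %in% rownames(out$table))
  expect_equal(out$table["s1", "X a"], 11L)
  # trace contamination at or below the floor does not trigger removal:
  # permuting the order changes the result on this fixture
  tr <- toy_hits()
  tr$neg$size <- 4L  # below the floor
  tab2 <- tabulate_hits(tr, toy_sheet(), "species", 95)
  keep <- remove_control_taxa(apply_noise_floor(tab2, 5), "neg")
  expect_true("Z c" %in% colnames(keep$table))        # floored first: kept
  flip <- apply_noise_floor(remove_control_taxa(tab2, "neg")$table, 5)
  expect_false("Z c" %in% colnames(flip))             # removed if order flipped
  expect_error(remove_control_taxa(fl, "nope"), "not in table")
})

test_that("filters only ever remove reads", {
  tab <- tabulate_hits(toy_hits(), toy_sheet(), "species", 95)
  fl <- apply_noise_floor(tab, 5)
  out <- remove_control_taxa(fl, "neg")$table
  shared_r <- rownames(out); shared_c <- colnames(out)
  expect_true(all(out <= tab[shared_r, shared_c]))
})

test_that("detection statistics match hand computation on a two-replicate site", {
  # site with field replicates detecting {A, B} and {B, C}
  sheet <- sample_sheet(data.frame(
    sample_id = c("r1", "r2"), index_f = c(strrep("A", 20), strrep("C", 20)),
    index_r = c(strrep("T", 20), strrep("G", 20)), marker = "edna",
    site_id = "s", elevation_m = 500, field_replicate = c(1, 2),
    rpa_replicate = 1, is_negative_control = FALSE))
  tab <- matrix(c(10L, 0L, 8L, 9L, 0L, 7L), nrow = 2,
                dimnames = list(c("r1", "r2"), c("A", "B", "C")))
  attr(tab, "rank") <- "species"
  st <- detection_stats(tab, sheet)
  expect_equal(st$mean_species_per_indexed_sample, 2)
  expect_equal(st$mean_species_per_site, 3)
  expect_equal(st$pct_increase, 50)
  # single sample per site everywhere -> no increase
  sheet1 <- sheet[1, ]; class(sheet1) <- class(sheet)
  st1 <- detection_stats(tab[1, , drop = FALSE], sheet1)
  expect_equal(st1$pct_increase, 0)
  # replication gain splits between field and RPA replicates
  expect_equal(st$attribution_field_pct, 100)  # only field replicates here
})

test_that("the printed detection means give the published ~68% increase", {
  expect_equal(round(richness_gain_pct(1.74, 2.92)), 68)
})

test_that("elevational summaries log means over all replicates", {
  sheet <- sample_sheet(data.frame(
    sample_id = c("a", "b"), index_f = c(strrep("A", 20), strrep("C", 20)),
    index_r = c(strrep("T", 20), strrep("G", 20)), marker = "edna",
    site_id = "s", elevation_m = 400, field_replicate = c(1, 2),
    rpa_replicate = 1, is_negative_control = FALSE))
  tab <- matrix(c(0L, 8L, 0L, 0L, 1L, 1L), nrow = 2,
                dimnames = list(c("a", "b"), c("X", "Y", "W")))
  es <- elevational_summary(tab, sheet, c(0, 800, 1600))
  x <- es[es$species == "X" & !is.na(es$mean_count) & es$mean_count > 0, ]
  expect_equal(x$mean_count, 4)            # zeros included in the mean
  expect_equal(x$ln_mean_count, log(4), tolerance = 1e-12)
  y <- es[es$species == "Y", ]
  expect_true(all(is.na(y$ln_mean_count)))  # absent, not -Inf
  w <- es[es$species == "W" & es$mean_count > 0, ]
  expect_equal(w$ln_mean_count, 0)          # ln(1) = 0 distinct from absent
  expect_error(elevational_summary(tab, sheet, c(800, 800)), "increasing")
})
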