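aln_from <- function(rows) do.call(rbind, strsplit(rows, ""))

test_that("gap-rich columns are trimmed with a strict > 50% rule", {
  rows <- c("A-CG-", "A-CGT", "AAC-T", "A-C-T", "AACGT")  # col2 60%, col4 40%
  m <- aln_from(rows)
  out <- trim_gappy_columns(m)
  expect_equal(ncol(out), 4)                   # only column 2 removed
  expect_equal(out[1, ], c("A", "C", "G", "-"))
  half <- aln_from(c("A-", "AC", "A-", "AC"))  # exactly 50% gaps retained
  expect_equal(ncol(trim_gappy_columns(half)), 2)
  clean <- aln_from(c("ACGT", "ACGT"))
  expect_identical(trim_gappy_columns(clean), clean)
  expect_error(trim_gappy_columns(c("ACG", "AC")), "ragged")
})

test_that("IUPAC consensus honours the minor-frequency threshold", {
  expect_equal(iupac_consensus(c(A = 1, C = 0, G = 0, T = 0)), "A")
  expect_equal(iupac_consensus(c(A = 0.6, C = 0.4, G = 0, T = 0)), "M")
  expect_equal(iupac_consensus(c(A = 0.97, C = 0.03, G = 0, T = 0)), "A")
  expect_equal(iupac_consensus(c(A = 0.3, C = 0.3, G = 0.2, T = 0.2), 0), "N")
  expect_error(iupac_consensus(c(A = 0, C = 0, G = 0, T = 0)), "all-gap")
})

test_that("profile frequencies sum to one among non-gap rows", {
  m <- aln_from(c("ACGT", "AC-T", "GCGA"))
  p <- alignment_profile(m)
  expect_equal(rowSums(p[, c("A", "C", "G", "T")]), rep(1, 4))
  expect_equal(p$gap_fraction[3], 1 / 3)
  expect_equal(p$conservation[2], 1)
})

test_that("elongation is exhaustive, ranked, and matches a brute-force oracle", {
  set.seed(161)
  base <- rand_seq(60)
  rows <- replicate(8, base)
  # one polymorphic column just left of the seed
  m <- aln_from(rows)
  seed_iv <- c(25, 47)  # 22-base seed
  m[1:4, 24] <- "A"; m[5:8, 24] <- "G"
  cand <- elongate_primer(m, seed_iv, "both", c(25, 30), max_degeneracy = 3)
  # oracle: enumerate every window containing the seed at each length
  oracle <- list()
  prof <- alignment_profile(m)
  for (L in 25:30) for (a in 0:(L - 22)) {
    s <- seed_iv[1] - a; e <- s + L
    if (s < 0 || e > 60) next
    code <- vapply((s + 1):e, function(j)
      iupac_consensus(prof[j, c("A", "C", "G", "T")]), "")
    oracle[[length(oracle) + 1]] <- data.frame(
      start = s, end = e, seq = paste(code, collapse = ""),
      deg = sum(!code %in% c("A", "C", "G", "T")),
      cons = mean(prof$conservation[(s + 1):e]))
  }
  ob <- do.call(rbind, oracle)
  ob <- ob[ob$deg <= 3, ]
  ob <- ob[order(ob$deg, -ob$cons, -(ob$end - ob$start), ob$start), ]
  expect_equal(nrow(cand), nrow(ob))
  expect_equal(cand$sequence, ob$seq)
  expect_equal(cand$start, ob$start)
  # the winner avoids the polymorphic column (0-based column 23) when an
  # equally long window without it exists
  top_clean <- cand[cand$n_degenerate == 0, ][1, ]
  expect_gte(top_clean$start, 24)
  expect_equal(cand$n_degenerate[1], 0)
  # identical rows: top candidate has zero degeneracies, max conservation
  clean <- elongate_primer(aln_from(replicate(5, base)), seed_iv, "both")
  expect_equal(clean$n_degenerate[1], 0)
  expect_equal(clean$mean_conservation[1], 1)
  # ranking is a total order: reruns agree
  expect_identical(elongate_primer(m, seed_iv, "both"), cand)
})

test_that("seed length interacts with the target range at the boundaries", {
  set.seed(162)
  m <- aln_from(rep(rand_seq(50), 4))
  # 30-base seed with range [25, 30]: only the identity candidate
  one <- elongate_primer(m, c(10, 40), "both")
  expect_equal(nrow(one), 1)
  expect_equal(one$length, 30)
  expect_equal(one$start, 10)
  expect_error(elongate_primer(m, c(5, 40), "both"), "exceeds")
  # direction restriction: 5prime extensions keep the seed's right edge
  d5 <- elongate_primer(aln_from(rep(rand_seq(60), 4)), c(30, 52), "5prime")
  expect_gt(nrow(d5), 1)
  expect_true(all(d5$end == 52))
})
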