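make_db <- function(n = 30, len = 300, seed = 131) {
  set.seed(seed)
  reference_db(sprintf("GB%04d", seq_len(n)),
               data.frame(kingdom = "Metazoa", phylum = "Chordata",
                          class = "Amphibia", order = "Anura", family = "F",
                          genus = sprintf("G%02d", seq_len(n)),
                          species = sprintf("G%02d sp", seq_len(n))),
               vapply(seq_len(n), function(i) rand_seq(len), ""))
}

test_that("k-mer prescreen ranks the true source first", {
  db <- make_db()
  q <- db$seq[7]
  expect_equal(kmer_prescreen(q, db)[1], db$accession[7])
  # reverse-complement queries are found too
  expect_equal(kmer_prescreen(revcomp(q), db)[1], db$accession[7])
  # a sequence over a disjoint alphabet region shares nothing
  none <- strrep("AT", 60)
  hits <- kmer_prescreen(none, db, k = 21)
  expect_true(length(hits) == 0 || all(hits != db$accession[3]))
})

test_that("prescreen top-1 agrees with exhaustive alignment on noisy queries", {
  db <- make_db(40, 280, seed = 132)
  set.seed(133)
  agree <- 0; trials <- 60
  for (i in seq_len(trials)) {
    src <- sample.int(nrow(db), 1)
    q <- mutate_k(substr(db$seq[src], 11, 260), sample(2:8, 1))
    exhaustive <- vapply(db$seq, function(s) align_identity(q, s)$score, 0)
    best_full <- db$accession[which.max(exhaustive)]
    pres <- kmer_prescreen(q, db, top_n = 1)
    agree <- agree + as.integer(length(pres) == 1 && pres == best_full)
  }
  expect_gte(agree / trials, 0.95)
})

test_that("best hit thresholds behave independently and ties are deterministic", {
  db <- make_db(10, 200, seed = 134)
  # query at ~96% identity to record 4: assigned at 95, unassigned at 99
  q <- mutate_k(db$seq[4], 8, seed = 135)
  bh <- best_hit(q, db)
  expect_equal(bh$hit$accession, db$accession[4])
  expect_true(bh$pass[["95"]])
  expect_false(bh$pass[["99"]])
  # exact member of the db: 100% identity at both thresholds
  bh2 <- best_hit(db$seq[4], db)
  expect_equal(bh2$hit$percent_identity, 100)
  expect_true(all(bh2$pass))
  # two accessions with identical sequence and species: lowest accession wins
  db2 <- db
  db2$seq[9] <- db2$seq[8]; db2$species[9] <- db2$species[8]
  db2$genus[9] <- db2$genus[8]
  bh3 <- best_hit(db2$seq[8], db2)
  expect_equal(bh3$hit$accession, min(db2$accession[8:9]))
  # local provenance outranks base on exact ties
  db3 <- db2; db3$provenance[9] <- "local"
  expect_equal(best_hit(db3$seq[8], db3)$hit$provenance, "local")
  expect_error(best_hit(q, db[0, ]), "empty")
})

test_that("assignment tables conserve sizes and respect threshold monotonicity", {
  db <- make_db(12, 250, seed = 136)
  set.seed(137)
  seqs <- vapply(1:30, function(i) {
    src <- sample.int(12, 1)
    mutate_k(db$seq[src], sample(0:12, 1))
  }, "")
  dr <- dereplicate(seq_records(sprintf("q%02d", 1:30), seqs))
  hits <- assign_queries(dr, db)
  expect_equal(sum(hits$size), 30)
  expect_true(all(hits$pass99 <= hits$pass95))  # 99-set nested in 95-set
  # repeated runs produce identical hit tables
  expect_identical(assign_queries(dr, db), hits)
})
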