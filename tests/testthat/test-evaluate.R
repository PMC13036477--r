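test_that("risk ratio and Wald interval match the closed form to 1e-12", {
  set.seed(141)
  for (k in 1:25) {
    n1 <- sample(50:5000, 1); x1 <- sample(seq_len(n1), 1)
    n2 <- sample(50:5000, 1); x2 <- sample(seq_len(n2), 1)
    rr <- risk_ratio(x1, n1, x2, n2)
    se <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
    point <- (x1 / n1) / (x2 / n2)
    expect_equal(rr$rr, point, tolerance = 1e-12)
    expect_equal(rr$ci_low, exp(log(point) - qnorm(0.975) * se), tolerance = 1e-12)
    expect_equal(rr$ci_high, exp(log(point) + qnorm(0.975) * se), tolerance = 1e-12)
    expect_true(rr$ci_low <= rr$rr && rr$rr <= rr$ci_high)
  }
  # null case: equal proportions
  eq <- risk_ratio(50, 100, 100, 200)
  expect_equal(eq$rr, 1)
  expect_true(eq$ci_low < 1 && eq$ci_high > 1)
  expect_error(risk_ratio(10, 100, 0, 100), "undefined")
})

test_that("risk ratio is antisymmetric and its CI narrows with n", {
  a <- risk_ratio(80, 100, 40, 100)
  b <- risk_ratio(40, 100, 80, 100)
  expect_equal(a$rr, 1 / b$rr, tolerance = 1e-12)
  expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
  expect_equal(a$ci_high, 1 / b$ci_low, tolerance = 1e-12)
  widths <- vapply(c(1, 5, 25, 125), function(f) {
    r <- risk_ratio(80 * f, 100 * f, 40 * f, 100 * f)
    r$ci_high - r$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("scoring splits class reads by checklist membership on stated denominators", {
  tab <- matrix(c(500L, 300L, 150L, 50L), nrow = 1,
                dimnames = list("s1", c("Good a", "Good b", "Bad x", "Cow z")))
  attr(tab, "rank") <- "species"
  attr(tab, "taxa") <- data.frame(
    taxon = colnames(tab),
    class = c("Amphibia", "Amphibia", "Amphibia", "Mammalia"))
  chk <- checklist(c("Good a", "Good b"))
  s <- score_assignments(tab, chk)
  expect_equal(s$n_total_reads_above_threshold, 1000)
  expect_equal(s$n_target_reads, 950)        # bycatch excluded from class reads
  expect_equal(s$pct_target_of_total, 95)
  expect_equal(s$n_correct, 800)
  expect_equal(s$pct_correct, 100 * 800 / 950)
  expect_equal(s$taxa_incorrect, "Bad x")
  # all assigned taxa on the checklist -> 100% correct
  s2 <- score_assignments(tab, checklist(c("Good a", "Good b", "Bad x")))
  expect_equal(s2$pct_correct, 100)
  empty <- tab; empty[] <- 0L
  expect_error(score_assignments(empty, chk), "empty")
})

test_that("identical databases compare at RR 1 and reports self-recompute", {
  db <- community_db(simulate_references(6, divergence = 0.1, seed = 151))
  set.seed(152)
  seqs <- vapply(1:20, function(i) mutate_k(substr(db$seq[sample(6, 1)], 30, 250),
                                            sample(0:3, 1)), "")
  dr <- dereplicate(seq_records(sprintf("q%02d", 1:20), seqs))
  hits <- list(s1 = assign_queries(dr, db))
  sheet <- sample_sheet(data.frame(
    sample_id = "s1", index_f = strrep("A", 20), index_r = strrep("T", 20),
    marker = "edna", site_id = "x", elevation_m = 100, field_replicate = 1,
    rpa_replicate = 1, is_negative_control = FALSE))
  chk <- checklist(db$species[db$class == "Amphibia"])
  rep <- compare_databases(hits, hits, sheet, chk)
  expect_true(all(rep$comparisons$rr == 1))
  sc <- rep$scores
  expect_equal(sc$pct_correct, 100 * sc$n_correct / sc$n_target_reads)
  # mismatched query sets are refused
  hits2 <- hits; hits2$s1 <- hits2$s1[-1, ]
  expect_error(compare_databases(hits, hits2, sheet, chk), "query set")
})
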