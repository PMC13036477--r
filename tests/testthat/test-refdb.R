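test_that("simple-dialect headers parse to full lineages and round-trip", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">LOC001|Animalia|Chordata|Amphibia|Anura|Bufonidae|Rhinella|Rhinella horribilis",
    "ACGTACGT",
    ">LOC002|Animalia|Chordata|Amphibia|Anura|Hylidae|Boana|",
    "ACGTACGA"), f)
  db <- parse_reference_fasta(f, "simple")
  expect_equal(db$species[1], "Rhinella horribilis")
  expect_equal(db$genus[1], "Rhinella")
  expect_equal(db$class, c("Amphibia", "Amphibia"))
  expect_equal(db$species[2], "UNKNOWN")  # partial data tolerated
  expect_equal(db$genus[2], "Boana")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(db, out)
  back <- parse_reference_fasta(out, "simple")
  expect_identical(as.data.frame(back), as.data.frame(db))
})

test_that("midori2-style headers parse tolerantly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">AB612242.1 root_1;class_Amphibia_20;order_Anura_30;family_Bufonidae_40;genus_Rhinella_50;species_Rhinella horribilis_60",
    "ACGT",
    ">XY000001.1 root_1;garbage-token;genus_Boana_70",
    "ACGA"), f)
  expect_warning(db <- parse_reference_fasta(f, "midori2"), "UNKNOWN")
  expect_equal(db$species[1], "Rhinella horribilis")
  expect_equal(db$accession[1], "AB612242.1")
  expect_equal(db$genus[2], "Boana")
  expect_equal(db$species[2], "UNKNOWN")
  writeLines(c(">A.1 x", "AC", ">A.1 y", "GT"), f)
  expect_error(suppressWarnings(parse_reference_fasta(f, "midori2")),
               "duplicate accession")
})

test_that("augmentation adds local records, skips duplicates, is idempotent", {
  base <- reference_db(
    sprintf("GB%03d", 1:100),
    data.frame(kingdom = "Metazoa", phylum = "Chordata", class = "Amphibia",
               order = "Anura", family = "F", genus = sprintf("G%03d", 1:100),
               species = sprintf("G%03d sp", 1:100)),
    vapply(1:100, function(i) rand_seq(80), ""))
  set.seed(121)
  bars <- data.frame(local_id = sprintf("BC%02d", 1:17),
                     species = sprintf("Novus sp%02d", 1:17),
                     seq = vapply(1:17, function(i) rand_seq(80), ""),
                     stringsAsFactors = FALSE)
  db <- augment(base, bars)
  expect_equal(nrow(db), 117)
  expect_equal(sum(db$provenance == "local"), 17)
  expect_true(all(startsWith(db$accession[db$provenance == "local"], "LOCAL_")))
  expect_equal(db$genus[db$provenance == "local"][1], "Novus")
  # idempotent: re-adding the same barcodes changes nothing
  expect_message(db2 <- augment(db, bars), "skipping")
  expect_identical(as.data.frame(db2), as.data.frame(db))
  # identity on the empty barcode list
  expect_identical(augment(base, bars[0, ]), base)
  # local id collision
  bars2 <- bars; bars2$local_id[2] <- bars2$local_id[1]
  expect_error(augment(base, bars2), "collision")
})

test_that("lineage invariants tie species to genus", {
  l <- lineage(species = "Rhinella horribilis")
  expect_equal(unname(l["genus"]), "Rhinella")
  expect_error(lineage(genus = "Boana", species = "Rhinella horribilis"),
               "does not match")
  expect_error(reference_db(c("a", "a"),
                            data.frame(kingdom = 1, phylum = 1, class = 1,
                                       order = 1, family = 1, genus = "G",
                                       species = "G s")[c(1, 1), ],
                            c("AC", "GT")),
               "duplicate accession")
})
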