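test_that("read filter drops strictly below the threshold and is idempotent", {
  tb <- make_table(list(c(4999, 4000, 1000),        # 9999 -> dropped
                        c(5000, 4000, 1000),        # 10000 -> kept
                        c(100000, 60639, 10000)),   # 170639 -> kept
                   dates = c("2015-01-05", "2015-01-12", "2015-01-19"))
  suppressMessages(f <- filter_min_reads(tb))
  expect_setequal(rownames(f$counts), c("s2", "s3"))
  expect_identical(filter_min_reads(f)$counts, f$counts)

  tb2 <- make_table(list(c(5000, 0), c(10893, 0), c(170639, 0)),
                    dates = c("2015-01-05", "2015-01-12", "2015-01-19"))
  suppressMessages(f2 <- filter_min_reads(tb2))
  expect_equal(nrow(f2$counts), 2)
  expect_error(filter_min_reads(make_table(list(c(1, 1)), "2015-01-05")),
               "below the read threshold")
})

test_that("filtering a replicate's primary promotes the surviving replicate", {
  tb <- make_table(list(c(3000, 3000),        # primary, below threshold
                        c(8000, 8000),        # replicate, kept
                        c(9000, 9000)),       # second replicate, kept
                   dates = rep("2015-01-05", 3),
                   replicate_of = c(NA, "s1", "s1"))
  suppressMessages(f <- filter_min_reads(tb))
  expect_setequal(rownames(f$counts), c("s2", "s3"))
  expect_true(is.na(f$meta$replicate_of[f$meta$sample_id == "s2"]))
  expect_equal(f$meta$replicate_of[f$meta$sample_id == "s3"], "s2")
  m <- merge_replicates(f)
  expect_equal(nrow(m$counts), 1)
})

test_that("replicate merging averages relative abundances", {
  tb <- make_table(list(c(10, 90), c(30, 70)),
                   dates = c("2015-01-05", "2015-01-05"),
                   replicate_of = c(NA, "s1"))
  m <- merge_replicates(tb)
  expect_equal(unname(m$counts["s1", ]), c(0.2, 0.8))
  expect_true(m$proportions)
  expect_equal(unname(rowSums(m$counts)), 1, tolerance = 1e-12)

  # singleton passes through; identical replicates are a fixed point
  single <- merge_replicates(make_table(list(c(25, 75)), "2015-01-05"))
  expect_equal(unname(single$counts[1, ]), c(0.25, 0.75))
  tri <- make_table(list(c(2, 8), c(2, 8), c(2, 8)),
                    dates = rep("2015-01-05", 3),
                    replicate_of = c(NA, "s1", "s1"))
  expect_equal(unname(merge_replicates(tri)$counts[1, ]), c(0.2, 0.8))

  bad <- make_table(list(c(1, 1), c(1, 1)),
                    dates = c("2015-01-05", "2015-01-12"),
                    replicate_of = c(NA, "s1"))
  expect_error(merge_replicates(bad), "spans plants or dates")
})

test_that("species aggregation sums shared labels and conserves totals", {
  tb <- make_table(list(c(5, 7, 3), c(2, 4, 6)),
                   dates = c("2015-01-05", "2015-01-12"),
                   taxa = c("ASV1", "ASV2", "ASV3"))
  tax <- data.frame(taxon_id = c("ASV1", "ASV2", "ASV3"),
                    Kingdom = "Bacteria", Phylum = "p", Class = "c",
                    Order = "o", Family = "f", Genus = "g",
                    Species = c("midas_s_4", "midas_s_4", NA))
  agg <- aggregate_to_species(tb, tax)
  expect_equal(unname(agg$counts[, "midas_s_4"]), c(12, 6))
  expect_equal(unname(agg$counts[, "ASV3"]), c(3, 6))     # genus-only ASV kept
  expect_identical(rowSums(agg$counts), rowSums(tb$counts))

  # no shared labels: identity shape
  tax$Species <- c("a", "b", "c")
  expect_equal(dim(aggregate_to_species(tb, tax)$counts), dim(tb$counts))
  expect_error(aggregate_to_species(tb, tax[-1, ]), "missing from taxonomy")
})

test_that("abundance retention uses a strict threshold on the per-sample max", {
  # 0.06% in one sample kept; exactly 0.05% everywhere dropped; all-zero dropped
  n <- 10000
  tb <- make_table(list(c(6, 5, 0, n - 11), c(0, 5, 0, n - 5)),
                   dates = c("2015-01-05", "2015-01-12"))
  kept <- retain_abundant_species(tb, threshold = 0.0005)
  expect_true("t1" %in% kept)    # 6/10000 = 0.06%
  expect_false("t2" %in% kept)   # exactly 0.05%
  expect_false("t3" %in% kept)   # all zero
  expect_true("t4" %in% kept)
})

test_that("table round trips through disk are lossless", {
  dir <- withr::local_tempdir()
  tb <- make_table(list(c(5L, 7L), c(11000L, 2L)),
                   dates = c("2015-01-05", "2015-01-12"))
  cf <- file.path(dir, "counts.tsv")
  write_count_table(tb$counts, cf)
  expect_identical(read_count_table(cf), tb$counts)
  expect_identical(read_count_table(cf, taxa_as_rows = FALSE), tb$counts)

  mf <- file.path(dir, "meta.csv")
  write_metadata(tb$meta, mf)
  m2 <- read_metadata(mf)
  expect_identical(m2$sample_id, tb$meta$sample_id)
  expect_identical(as.Date(m2$date), tb$meta$date)
  expect_identical(m2$replicate_of, tb$meta$replicate_of)

  tf <- file.path(dir, "tax.tsv")
  tax <- data.frame(taxon_id = c("t1", "t2"), Kingdom = "Bacteria",
                    Phylum = "p", Class = "c", Order = "o", Family = "f",
                    Genus = "g", Species = c("midas_s_4", NA))
  write_taxonomy(tax, tf)
  expect_identical(read_taxonomy(tf), tax)
})
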