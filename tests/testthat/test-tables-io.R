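test_that("TSV OTU tables parse with OTUs as rows and samples as columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2",
               "OTU1\t0\t5",
               "OTU2\t3\t1",
               "OTU3\t2\t0"), f)
  tab <- read_otu_table(f)
  expect_identical(dim(tab), c(2L, 3L))
  expect_identical(rownames(tab), c("s1", "s2"))
  expect_identical(tab["s2", "OTU1"], 5L)
})

test_that("structural errors are raised for duplicate ids and bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1", "OTU1\t1", "OTU1\t2"), f)
  expect_error(read_otu_table(f), "duplicated otu_id")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2", "OTU1\t1\tabc"), g)
  expect_error(read_otu_table(g), "malformed numeric cell")
  m <- random_counts()
  rownames(m) <- rep("dup", nrow(m))
  expect_error(otu_table(m), "duplicated sample ids")
  expect_error(otu_table(matrix(-1, 1, 1, dimnames = list("s", "o"))),
               "non-negative")
})

test_that("BIOM and TSV serializations round-trip to the same table", {
  set.seed(11)
  tab <- random_counts(4, 6)
  tf <- withr::local_tempfile(fileext = ".tsv")
  bf <- withr::local_tempfile(fileext = ".biom")
  write_otu_table(tab, tf, "tsv")
  write_otu_table(tab, bf, "biom")
  t1 <- read_otu_table(tf)
  t2 <- read_otu_table(bf, format = "biom")
  expect_identical(t1, tab)
  expect_identical(t2[rownames(tab), colnames(tab)], tab)
})

test_that("minimum-read filter removes below-threshold OTUs and conserves reads", {
  tab <- otu_table(matrix(c(1L, 0L,   # OTU with a single read: removed
                            1L, 1L,   # exactly 2 reads: retained
                            0L, 0L,   # zero reads: removed
                            5L, 3L),
                          nrow = 2,
                          dimnames = list(c("s1", "s2"), paste0("OTU", 1:4))))
  res <- filter_min_reads(tab, 2)
  expect_setequal(colnames(res$counts), c("OTU2", "OTU4"))
  expect_setequal(res$report$otu_id, c("OTU1", "OTU3"))
  expect_true(all(res$report$reason == "below_min_reads"))
  expect_equal(attr(res$report, "reads_removed") + sum(res$counts), sum(tab))

  empty <- otu_table(matrix(integer(0), nrow = 2, ncol = 0,
                            dimnames = list(c("s1", "s2"), character(0))))
  res0 <- filter_min_reads(empty)
  expect_identical(ncol(res0$counts), 0L)
  expect_identical(nrow(res0$report), 0L)
})

test_that("non-target filter removes blocklisted lineages and flags low identity", {
  tab <- random_counts(3, 4)
  tax <- data.frame(
    otu_id = colnames(tab),
    lineage = c("d__Bacteria; p__Cyanobacteria; c__Chloroplast",
                "d__Bacteria; p__Proteobacteria; g__Pantoea",
                "d__Plantae; g__Mitochondria",
                "d__Bacteria; p__Firmicutes; g__Bacillus"),
    confidence = c(0.9, 0.10, 0.95, 0.99),
    annotations = "", stringsAsFactors = FALSE)
  res <- filter_nontarget(tab, tax)
  expect_setequal(colnames(res$counts), c("OTU2", "OTU4"))
  removed <- res$report[res$report$removed, ]
  expect_setequal(removed$otu_id, c("OTU1", "OTU3"))
  expect_true(all(removed$reason == "non_target"))
  flagged <- res$report[!res$report$removed, ]
  expect_identical(flagged$otu_id, "OTU2")      # low identity, kept in table
  expect_identical(flagged$reason, "flagged_low_identity")
  expect_error(filter_nontarget(tab, tax[-2, ]), "OTU2")
})

test_that("the two filters commute when their criteria are independent", {
  set.seed(7)
  for (i in 1:25) {
    tab <- random_counts(4, 10, lambda = 1.5)
    tax <- tiny_taxonomy(colnames(tab))
    contam <- sample(ncol(tab), 2)
    tax$lineage[contam] <- "d__Bacteria; p__Cyanobacteria; c__Chloroplast"
    a <- filter_nontarget(filter_min_reads(tab)$counts, tax)$counts
    b <- filter_min_reads(filter_nontarget(tab, tax)$counts)$counts
    expect_identical(sort(colnames(a)), sort(colnames(b)))
  }
})

test_that("metadata validation enforces the design-grid vocabulary", {
  meta <- tiny_meta()
  expect_silent(validate_metadata(meta))
  bad <- meta
  bad$substrate[bad$compartment == "seed"][1] <- "soil"
  expect_error(validate_metadata(bad), "substrate 'none'")
  bad2 <- meta
  bad2$compartment[1] <- "leaf"
  expect_error(validate_metadata(bad2), "unknown compartment")
  expect_error(validate_metadata(meta[-1, ],
                                 matrix(0L, 1, 1, dimnames = list(meta$sample_id[1], "o"))),
               "without metadata")
})

test_that("conventional sample names parse into metadata", {
  got <- parse_sample_names(c("maize soil shoot #2", "maize seed #1"))
  expect_identical(got$species, c("maize", "maize"))
  expect_identical(got$substrate, c("soil", "none"))
  expect_identical(got$compartment, c("shoot", "seed"))
  expect_identical(got$replicate, c(2L, 1L))
  expect_error(parse_sample_names("maize soil seed #1"), "must not carry a substrate")
  expect_error(parse_sample_names("nonsense"), "unparseable")
})
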