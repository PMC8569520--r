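test_that("Shannon H matches closed forms and is maximal at uniform", {
  expect_equal(shannon_h(rep(0.25, 4)), log(4))
  expect_equal(shannon_h(c(1, 0, 0)), 0)
  expect_equal(shannon_h(c(0.5, 0.25, 0.25)), 1.03972, tolerance = 1e-5)
  expect_equal(shannon_h(c(2, 3, 5)), shannon_h(c(0.2, 0.3, 0.5)))  # counts ok
  expect_true(is.na(shannon_h(c(0, 0))))
  expect_equal(shannon_h(rep(1, 8), base = 2), 3)
  set.seed(13)
  for (i in 1:50) {
    p <- random_simplex(6)
    expect_lte(shannon_h(p), shannon_h(rep(1 / 6, 6)) + 1e-12)
  }
})

test_that("Shannon H agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (i in 1:20) {
    x <- rpois(12, 5)
    if (sum(x) == 0) next
    expect_equal(shannon_h(x), unname(vegan::diversity(x, "shannon")))
  }
})

test_that("richness counts strictly positive entries", {
  expect_identical(richness(c(0, 3, 1)), 2L)
  expect_identical(richness(rep(0, 5)), 0L)
  set.seed(29)
  for (i in 1:25) {                    # rarefaction can only lose OTUs
    x <- rpois(15, 3)
    expect_lte(richness(rarefy(x, 10)), richness(x))
  }
})

test_that("Bray-Curtis matches hand values, bounds and symmetry", {
  p <- random_simplex(5)
  expect_equal(bray_curtis(p, p), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)          # disjoint support
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5)
  set.seed(37)
  for (i in 1:50) {
    x <- random_simplex(7); y <- random_simplex(7)
    b <- bray_curtis(x, y)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b, bray_curtis(y, x))
  }
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- t(replicate(6, random_simplex(10)))
  rownames(m) <- paste0("s", 1:6)
  d <- bray_curtis_matrix(m)
  expect_equal(as.dist(d), vegan::vegdist(m, "bray"), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
})

test_that("UPGMA clustering matches hclust average linkage on tie-free matrices", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    d <- random_distance_matrix(n)
    tree <- cluster_samples(d, "upgma")
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(tree$height, ref$height, tolerance = 1e-12)
    # same topology: identical cophenetic distances
    expect_equal(cophenetic(stats::as.hclust(tree)), cophenetic(ref),
                 tolerance = 1e-12)
    # UPGMA merge heights are monotone non-decreasing
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("clustering is deterministic under ties and label permutation", {
  # perfectly tied square: lexicographically smallest pair merges first
  d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tree <- cluster_samples(d)
  expect_identical(leaf_order(tree)[1:2], c("a", "b"))
  # permuting the input rows relabels nothing
  set.seed(47)
  d2 <- random_distance_matrix(6)
  perm <- sample(6)
  t1 <- cluster_samples(d2)
  t2 <- cluster_samples(d2[perm, perm])
  expect_identical(leaf_order(t1), leaf_order(t2))
  expect_equal(t1$height, t2$height)
  # identical samples merge at height zero
  d3 <- random_distance_matrix(3)
  d3["L1", "L2"] <- d3["L2", "L1"] <- 0
  expect_equal(cluster_samples(d3)$height[1], 0)
  expect_error(cluster_samples(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
})

test_that("linkage trees export to Newick with all leaves", {
  d <- random_distance_matrix(5)
  nwk <- as_newick(cluster_samples(d))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(d))
})

test_that("lineage rank extraction handles prefixes and missing ranks", {
  lin <- c("d__Bacteria; p__Proteobacteria; g__Pantoea",
           "d__Bacteria; g__Unplaced",
           "k__Fungi; p__Ascomycota")
  expect_identical(lineage_rank(lin, "phylum"),
                   c("Proteobacteria", "unknown", "Ascomycota"))
  expect_identical(lineage_rank(lin, "domain"), c("Bacteria", "Bacteria", "Fungi"))
  expect_identical(lineage_rank(lin, "genus"), c("Pantoea", "Unplaced", "unknown"))
})

test_that("phylum composition sums to one per group and buckets unknowns", {
  props <- rbind(s1 = c(0.4, 0.6, 0), s2 = c(0, 0.5, 0.5))
  colnames(props) <- paste0("OTU", 1:3)
  tax <- data.frame(otu_id = colnames(props),
                    lineage = c("d__B; p__Proteobacteria; g__X",
                                "d__B; p__Proteobacteria; g__Y",
                                "d__B; g__NoPhylum"),
                    confidence = 0.9, annotations = "")
  comp <- phylum_composition(props, tax, groups = c(s1 = "g1", s2 = "g2"))
  g1 <- comp[comp$group == "g1", ]
  expect_equal(g1$proportion[g1$phylum == "Proteobacteria"], 1)
  g2 <- comp[comp$group == "g2", ]
  expect_equal(g2$proportion[g2$phylum == "unknown"], 0.5)
  expect_equal(tapply(comp$proportion, comp$group, sum), c(g1 = 1, g2 = 1),
               ignore_attr = TRUE)
})

test_that("phylum aggregation commutes with replicate averaging", {
  set.seed(53)
  meta <- data.frame(sample_id = paste0("r", 1:3), species = "alpha",
                     compartment = "root", substrate = "soil",
                     replicate = 1:3, marker = "16S")
  for (i in 1:10) {
    props <- t(replicate(3, random_simplex(8)))
    dimnames(props) <- list(meta$sample_id, paste0("OTU", 1:8))
    tax <- data.frame(otu_id = colnames(props),
                      lineage = paste0("d__B; p__P", sample(1:3, 8, TRUE)),
                      confidence = 0.9, annotations = "")
    avg <- average_proportions(props, meta)
    a <- phylum_composition(avg$props, tax)            # aggregate after mean
    b <- phylum_composition(props, tax)                # mean after aggregate
    expect_equal(a$proportion[order(a$phylum)], b$proportion[order(b$phylum)])
  }
})
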