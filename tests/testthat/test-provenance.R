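test_that("seed references are the union of seed and spermosphere presence", {
  meta <- data.frame(
    sample_id = c("alpha.seed", "alpha.sperm", "beta.seed", "beta.sperm"),
    species = c("alpha", "alpha", "beta", "beta"),
    compartment = c("seed", "spermosphere", "seed", "spermosphere"),
    substrate = "none", replicate = 1, marker = "16S")
  props <- rbind(`alpha.seed`  = c(A = 0.6, B = 0.4, C = 0, D = 0),
                 `alpha.sperm` = c(A = 0, B = 0.5, C = 0.5, D = 0),
                 `beta.seed`   = c(A = 0, B = 0, C = 0, D = 0),
                 `beta.sperm`  = c(A = 0, B = 0, C = 0, D = 0))
  ref <- build_seed_reference(props, meta)
  expect_setequal(ref$alpha, c("A", "B", "C"))
  expect_identical(ref$beta, character(0))
  expect_identical(attr(ref, "empty_species"), "beta")
})

test_that("seed attribution computes OTU and read fractions against the reference", {
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  res <- seed_attribution(p, c("A", "C"))
  expect_equal(res$otu_fraction, 2 / 3)
  expect_equal(res$read_fraction, 0.7)
  expect_setequal(res$attributed_otus, c("A", "C"))
  # reference superset -> everything attributed; disjoint -> nothing
  expect_equal(seed_attribution(p, c("A", "B", "C", "Z"))$read_fraction, 1)
  expect_equal(seed_attribution(p, "Z")$otu_fraction, 0)
  empty <- seed_attribution(c(A = 0, B = 0), c("A"))
  expect_true(is.na(empty$otu_fraction))
  expect_identical(empty$n_present, 0L)
})

test_that("soil attribution subtracts the sand counterpart", {
  p <- c(A = 0.2, B = 0.3, C = 0.5)
  res <- soil_attribution(p, "A")
  expect_equal(res$otu_fraction, 2 / 3)
  expect_equal(res$read_fraction, 0.8)
  expect_setequal(res$attributed_otus, c("B", "C"))
  expect_equal(soil_attribution(p, c("A", "B", "C"))$read_fraction, 0)   # sand superset
  expect_equal(soil_attribution(p, character(0))$read_fraction, 1)       # empty sand
  # the soil-attributed set never intersects the sand counterpart,
  # and the seed-attributed set is always inside the reference
  set.seed(71)
  for (i in 1:25) {
    pv <- random_simplex(10)
    names(pv) <- paste0("o", 1:10)
    sand <- sample(names(pv), 4)
    ref <- sample(names(pv), 5)
    expect_length(intersect(soil_attribution(pv, sand)$attributed_otus, sand), 0)
    expect_true(all(seed_attribution(pv, ref)$attributed_otus %in% ref))
  }
})

test_that("sand counterparts are unions over replicates, never intersections", {
  meta <- data.frame(
    sample_id = c("a1", "a2", "b1"),
    species = c("alpha", "alpha", "beta"),
    compartment = "root", substrate = "sand", replicate = c(1, 2, 1),
    marker = "16S")
  counts <- rbind(a1 = c(X = 5L, Y = 0L, Z = 0L),
                  a2 = c(X = 0L, Y = 3L, Z = 0L),
                  b1 = c(X = 0L, Y = 0L, Z = 2L))
  sets <- sand_counterparts(counts, meta)
  expect_setequal(sets[["alpha|root"]], c("X", "Y"))   # union across reps
  expect_identical(sets[["beta|root"]], "Z")
})

test_that("common-OTU provenance classification follows the occupancy rules", {
  mk_occ <- function(ids, occ, n = 17L) {
    data.frame(otu_id = ids, n_present = as.integer(round(occ * n)),
               n_total = n, occupancy = occ, mean_abundance = 0.01)
  }
  soil_occ <- mk_occ(c("w", "x", "y", "z"), c(12 / 17, 12 / 17, 12 / 17, 5 / 17))
  sand_occ <- mk_occ(c("w", "x", "y", "z"), c(11 / 17, 0, 5 / 17, 12 / 17))
  got <- classify_common_provenance(soil_occ, sand_occ)
  lab <- setNames(got$label, got$otu_id)
  expect_identical(lab[["w"]], "seed")      # common on both substrates
  expect_identical(lab[["x"]], "soil")      # absent from every sand sample
  expect_identical(lab[["y"]], "neither")   # present on sand but not common there
  expect_false("z" %in% got$otu_id)         # not common on soil at all
})

test_that("the core seed-transmitted union equals brute force over compartments", {
  set.seed(73)
  species <- paste0("sp", 1:6)
  rows <- expand.grid(species = species, compartment = VEG_COMPARTMENTS,
                      stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = paste(rows$species, rows$compartment, sep = "."),
                     species = rows$species, compartment = rows$compartment,
                     substrate = "sand", replicate = 1, marker = "16S")
  for (trial in 1:20) {
    counts <- random_counts(nrow(meta), 15, lambda = 0.9)
    rownames(counts) <- meta$sample_id
    props <- to_proportions(counts)
    got <- core_seed_transmitted_union(props, meta)
    # brute force: an OTU is in the union iff some compartment has it everywhere
    expected <- character(0)
    for (otu in colnames(props)) {
      for (cpt in VEG_COMPARTMENTS) {
        sel <- meta$compartment == cpt
        if (all(props[sel, otu] > 0)) { expected <- c(expected, otu); break }
      }
    }
    expect_setequal(as.character(got), expected)
    per <- attr(got, "per_compartment")
    expect_setequal(as.character(got), unique(unlist(per)))
  }
})

test_that("provenance_matrix attributes the grid and flags schema rules", {
  meta <- tiny_meta()
  set.seed(79)
  counts <- random_counts(nrow(meta), 12, lambda = 5)
  rownames(counts) <- meta$sample_id
  prov <- provenance_matrix(counts, meta)
  # sand rows never get a soil attribution
  expect_true(all(is.na(prov$soil_read_fraction[prov$substrate == "sand"])))
  expect_true(all(!is.na(prov$soil_read_fraction[prov$substrate == "soil"])))
  expect_true(all(prov$seed_read_fraction >= 0 & prov$seed_read_fraction <= 1))
  # unknown remainder is 1 - attributed, per scheme
  expect_equal(prov$seed_unknown_read_fraction, 1 - prov$seed_read_fraction)
  # averages cover each compartment x substrate stratum once
  avg <- summarize_provenance(prov)
  expect_identical(nrow(avg), 6L)
  expect_true(all(avg$n_species == 2))
  # marker mixing is rejected
  meta2 <- rbind(meta, within(tiny_meta("ITS"), sample_id <- paste0(sample_id, "b")))
  counts2 <- random_counts(nrow(meta2), 5)
  rownames(counts2) <- meta2$sample_id
  expect_error(provenance_matrix(counts2, meta2), "single marker")
})

test_that("per-replicate mode yields one row per replicate", {
  meta <- tiny_meta()
  set.seed(83)
  counts <- random_counts(nrow(meta), 10, lambda = 5)
  rownames(counts) <- meta$sample_id
  per <- provenance_matrix(counts, meta, replicate_mode = "per_rep")
  pooled <- provenance_matrix(counts, meta, replicate_mode = "pooled")
  expect_identical(nrow(per), 2L * nrow(pooled))   # two reps per stratum
  expect_true(all(!is.na(per$replicate)))
  expect_true(all(is.na(pooled$replicate)))
})
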