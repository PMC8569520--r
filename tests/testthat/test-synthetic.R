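# a small grid keeps the generator tests fast
small_cfg <- function(...) {
  generator_config(n_species = 5, n_core_seed = 3, n_common_seed = 6,
                   n_species_seed = 1, n_soil_only = 20, n_contaminant = 4,
                   depth_meanlog = log(1500), depth_min = 400L,
                   markers = "16S", rng_seed = 7L, ...)
}

test_that("the generator emits the full design grid deterministically", {
  sim1 <- generate_community(small_cfg())
  sim2 <- generate_community(small_cfg())
  expect_identical(sim1$tables, sim2$tables)          # byte-identical rerun
  expect_identical(sim1$truth, sim2$truth)
  meta <- sim1$metadata
  # 5 species x (2 compartments x 2 reps + 3 compartments x 2 substrates x 3 reps)
  expect_identical(nrow(meta), 5L * (2L * 2L + 3L * 2L * 3L))
  expect_setequal(unique(meta$compartment), COMPARTMENTS)
  expect_true(all(meta$substrate[meta$compartment %in% c("seed", "spermosphere")] == "none"))
  expect_silent(validate_metadata(meta, sim1$tables[["16S"]]))
})

test_that("per-sample totals are non-negative integers matching drawn depths", {
  sim <- generate_community(small_cfg())
  tab <- sim$tables[["16S"]]
  expect_true(all(tab >= 0))
  expect_identical(storage.mode(tab), "integer")
  # every sample got a positive depth and ensure_presence gave each planted
  # community member at least one read (depths here always exceed community size)
  expect_true(all(rowSums(tab) > 0))
})

test_that("soil-only OTUs never appear in sand-grown or seed/spermosphere samples", {
  sim <- generate_community(small_cfg())
  tab <- sim$tables[["16S"]]
  labels <- sim$truth$otu_labels
  soil_ids <- labels$otu_id[labels$label == "soil_only"]
  meta <- sim$metadata
  non_soil <- meta$sample_id[meta$substrate != "soil"]
  expect_true(all(tab[non_soil, soil_ids] == 0))
})

test_that("contaminant OTUs carry blocklisted lineages end to end", {
  sim <- generate_community(small_cfg())
  labels <- sim$truth$otu_labels
  cont <- labels$otu_id[labels$label == "contaminant"]
  res <- filter_nontarget(sim$tables[["16S"]], sim$taxonomy)
  removed <- res$report$otu_id[res$report$removed]
  expect_setequal(intersect(colnames(sim$tables[["16S"]]), cont) , cont)
  expect_true(all(cont %in% removed))
  expect_length(setdiff(removed, cont), 0)    # and nothing else is removed
})

test_that("with zero dropout every transmitted OTU is in its species' seed reference", {
  sim <- generate_community(small_cfg())
  tab <- filter_nontarget(sim$tables[["16S"]], sim$taxonomy)$counts
  meta <- sim$metadata
  pooled <- pool_replicates(tab, meta)
  refs <- build_seed_reference(to_proportions(pooled$counts), pooled$metadata)
  labels <- sim$truth$otu_labels
  vertical <- labels$otu_id[labels$label %in% c("core_seed", "common_seed", "species_seed")]
  for (sp in unique(meta$species)) {
    veg <- meta$sample_id[meta$species == sp & meta$compartment %in% VEG_COMPARTMENTS]
    present <- colnames(tab)[colSums(tab[veg, , drop = FALSE]) > 0]
    expect_true(all(intersect(present, vertical) %in% refs[[sp]]))
  }
})

test_that("increasing carry-over increases the true vertical read fraction", {
  lo <- generate_community(small_cfg(carry_over = c(rhizosphere = 0.2, root = 0.2, shoot = 0.2),
                                     carry_over_core = c(rhizosphere = 0.2, root = 0.2, shoot = 0.2)))
  hi <- generate_community(small_cfg(carry_over = c(rhizosphere = 0.9, root = 0.9, shoot = 0.9),
                                     carry_over_core = c(rhizosphere = 0.9, root = 0.9, shoot = 0.9)))
  f <- function(sim) {
    st <- sim$truth$sample_truth
    mean(st$true_vertical_read_fraction[st$substrate == "soil"], na.rm = TRUE)
  }
  expect_gt(f(hi), f(lo))
})

test_that("marginal OTU proportions track the Dirichlet base abundances", {
  # many replicate samples of one fixed community
  set.seed(97)
  base <- rlnorm(12, 0, 1)
  expected <- base / sum(base)
  depth <- 600L
  draws <- replicate(1000, {
    g <- rgamma(12, shape = 50 * expected)
    p <- g / sum(g)
    as.integer(rmultinom(1, depth, p)) / depth
  })
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se + 1e-3))
})

test_that("recovery metrics are exact under perfect detection", {
  cfg <- no_noise_config(n_species = 5, n_core_seed = 3, n_common_seed = 6,
                         n_species_seed = 1, n_soil_only = 20, n_contaminant = 4,
                         markers = "16S", rng_seed = 11L)
  sim <- generate_community(cfg)
  tab <- filter_min_reads(sim$tables[["16S"]])$counts
  tab <- filter_nontarget(tab, sim$taxonomy)$counts
  prov <- provenance_matrix(tab, sim$metadata)
  rec <- evaluate_recovery(prov, tab, sim$metadata, sim$truth)
  expect_equal(rec$rmse, 0, tolerance = 1e-12)
  expect_equal(max(abs(rec$per_sample$signed_error), na.rm = TRUE), 0,
               tolerance = 1e-12)
})

test_that("seed-detection dropout causes systematic underestimation", {
  cfg <- small_cfg(dropout = 0.4)
  sim <- generate_community(cfg)
  tab <- filter_min_reads(sim$tables[["16S"]])$counts
  tab <- filter_nontarget(tab, sim$taxonomy)$counts
  prov <- provenance_matrix(tab, sim$metadata, replicate_mode = "per_rep")
  rec <- evaluate_recovery(prov, tab, sim$metadata, sim$truth)
  expect_lt(rec$bias, 0)
  expect_true(all(rec$per_sample$signed_error <= 1e-12, na.rm = TRUE))
  expect_identical(nrow(sim$truth$masked) > 0, TRUE)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_core_seed = 0, n_common_seed = 0,
                                n_species_seed = 0, n_soil_only = 0,
                                n_contaminant = 0), "no OTUs")
  expect_error(generator_config(dropout = 1), "< 1")
  expect_error(generator_config(carry_over = c(rhizosphere = 2, root = 0.5, shoot = 0.5)),
               "probabilities")
  expect_error(generator_config(n_species = 3, species = c("a", "b")), "length")
})
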