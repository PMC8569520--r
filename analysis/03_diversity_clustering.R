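#!/usr/bin/env Rscript
# Alpha diversity of the pooled inventories (Shannon H, richness per sample
# group) and the clustering branch: rarefy to per-compartment depths,
# normalise, average replicates, order samples by Bray-Curtis/UPGMA and
# export trees, distance matrices and binned abundance heatmap matrices.

suppressMessages(library(seedprov))

meta <- read_sample_metadata("results/data/metadata.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (m in MARKERS) {
  tab <- read_otu_table(file.path("results/filtered", paste0("filtered_", m, ".tsv")))
  mm <- meta[meta$marker == m & meta$sample_id %in% rownames(tab), ]

  # pooled inventories: per-sample-type mean diversity
  pooled <- pool_replicates(tab, mm)
  pp <- to_proportions(pooled$counts)
  pm <- pooled$metadata
  div <- data.frame(pm[, c("species", "compartment", "substrate")],
                    richness = apply(pp, 1, richness),
                    shannon_h = apply(pp, 1, shannon_h))
  write.table(div, file.path(out, paste0("alpha_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- aggregate(cbind(richness, shannon_h) ~ compartment + substrate, div, mean)
  cat(sprintf("\n%s mean per-species diversity by sample type:\n", m))
  print(agg, row.names = FALSE)

  # phylum composition of seeds and spermospheres across the panel
  seedish <- pm$compartment %in% SEED_COMPARTMENTS
  comp <- phylum_composition(pp[pm$sample_id[seedish], , drop = FALSE], tax,
                             groups = setNames(pm$compartment[seedish],
                                               pm$sample_id[seedish]))
  write.table(comp, file.path(out, paste0("phylum_seed_sperm_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # clustering branch on rarefied, averaged proportions
  rare <- rarefy_table(tab, mm, rarefaction_policy(rng_seed = 20240901L))
  avg <- average_proportions(to_proportions(rare), mm)
  for (cpt in VEG_COMPARTMENTS) {
    sel <- avg$metadata$compartment == cpt
    sub <- avg$props[avg$metadata$sample_id[sel], , drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (nrow(sub) < 2) next
    tree <- cluster_samples(bray_curtis_matrix(sub))
    as_newick(tree, file.path(out, paste0("tree_", m, "_", cpt, ".nwk")))
    ord <- leaf_order(tree)
    bins <- bin_matrix(sub[ord, , drop = FALSE])
    write.table(data.frame(sample_id = rownames(bins), bins, check.names = FALSE),
                file.path(out, paste0("bins_", m, "_", cpt, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # do sand- and soil-grown samples of one species sit as neighbours?
    sp_of <- avg$metadata$species[match(ord, avg$metadata$sample_id)]
    paired <- sum(sp_of[-1] == sp_of[-length(sp_of)])
    cat(sprintf("%s %s: %d of %d adjacent leaf pairs share a species\n",
                m, cpt, paired, length(ord) - 1))
  }
}
cat("\ndiversity tables, Newick trees and bin matrices written under", out, "\n")
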