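#!/usr/bin/env Rscript
# Occupancy analysis on the pooled inventories: common (>60% of species,
# strict) and core (100%) OTU sets per compartment and substrate, the ranked
# occupancy-abundance reports, and the core seed-transmitted union over the
# sand-grown vegetative compartments.

suppressMessages(library(seedprov))

meta <- read_sample_metadata("results/data/metadata.tsv")
out <- "results/occupancy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (m in MARKERS) {
  tab <- read_otu_table(file.path("results/filtered", paste0("filtered_", m, ".tsv")))
  mm <- meta[meta$marker == m & meta$sample_id %in% rownames(tab), ]
  pooled <- pool_replicates(tab, mm)
  pp <- to_proportions(pooled$counts)
  pm <- pooled$metadata

  strata <- unique(pm[, c("compartment", "substrate")])
  occ <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- pm$compartment == strata$compartment[i] & pm$substrate == strata$substrate[i]
    occupancy(pp, pm$sample_id[sel])
  })
  names(occ) <- paste(strata$compartment, strata$substrate, sep = ".")

  report <- occupancy_abundance_report(occ)
  write.table(report, file.path(out, paste0("occupancy_report_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("\n%s common (>60%%) and core (100%%) OTUs per stratum:\n", m))
  for (g in names(occ)) {
    cat(sprintf("  %-20s common %3d  core %3d\n", g,
                length(common_otus(occ[[g]])), length(core_otus(occ[[g]]))))
  }

  core_union <- core_seed_transmitted_union(pp, pm)
  write.table(data.frame(otu_id = as.character(core_union)),
              file.path(out, paste0("core_seed_transmitted_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s core seed-transmitted union across sand-grown compartments: %d OTUs\n",
              m, length(core_union)))
}
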