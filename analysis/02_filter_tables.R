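#!/usr/bin/env Rscript
# OTU-level exclusion filters per marker table: drop OTUs below two total
# reads, remove non-target lineages (chloroplast, mitochondria, plant
# ribosomes, protists) by blocklist, and flag low-identity OTUs for review
# instead of silently discarding them. Writes the filtered tables and the
# auditable filter reports.

suppressMessages(library(seedprov))

data_dir <- "results/data"
out <- "results/filtered"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tax <- read_taxonomy(file.path(data_dir, "taxonomy.tsv"))

for (m in MARKERS) {
  tab <- read_otu_table(file.path(data_dir, paste0("otu_", m, ".tsv")))
  f1 <- filter_min_reads(tab, 2)
  f2 <- filter_nontarget(f1$counts, tax)
  report <- rbind(f1$report, f2$report)
  write_otu_table(f2$counts, file.path(out, paste0("filtered_", m, ".tsv")))
  write.table(report, file.path(out, paste0("filter_report_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s: %d -> %d OTUs (%d below 2 reads, %d non-target removed, %d flagged low-identity); %d reads removed\n",
    m, ncol(tab), ncol(f2$counts), sum(f1$report$removed),
    sum(f2$report$removed), sum(!f2$report$removed),
    attr(f1$report, "reads_removed") + attr(f2$report, "reads_removed")))
}
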