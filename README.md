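# seedprov

Seed versus soil provenance attribution for juvenile plant microbiomes.

## The problem

Seedlings acquire microbes from two main sources: vertically, from the seed
interior and the seed-surface wash (spermosphere), and horizontally, from
the soil. Given multi-compartment amplicon OTU tables from a gnotobiotic
design — a panel of plant species grown in sealed jars on sterile sand
(seed is then the only inoculum) or field soil, profiled in seed,
spermosphere, rhizosphere, root and shoot with 16S and ITS markers —
`seedprov` attributes every OTU, and every read, of a juvenile-plant sample
to seed, soil, or unknown provenance using the deterministic set algebra
the design affords:

- an OTU present in a vegetative sample with present set *P* is
  **seed-attributed** when it also occurs in the same species' seed ∪
  spermosphere reference *R*: OTU fraction |*P* ∩ *R*| / |*P*|, read
  fraction Σ proportions over *P* ∩ *R*;
- an OTU in a soil-grown sample is **soil-attributed** when it was never
  observed in any sterile-sand replicate of the same species and
  compartment: *P* \ *S* with *S* the sand-counterpart union;
- an OTU is **common** in a group when its occupancy is strictly above 60%
  (on 17 species: at least 11), **core** at exactly 100%; OTUs core to any
  sand-grown compartment are *core and seed-transmitted*, and their union
  is the core seed-transmitted microbiome.

Around this inference the package implements the full supporting pipeline:
TSV/BIOM OTU-table, taxonomy and metadata I/O; the ≥2-read and non-target
(chloroplast/mitochondria/plant-ribosome/protist blocklist) OTU filters;
proportional normalization; per-compartment rarefaction that keeps
undersampled samples; pooled (sum-then-normalize) and averaged
(rarefy-normalize-average) replicate schemes; Shannon diversity, Bray–Curtis
dissimilarity and deterministic UPGMA sample ordering; occupancy–abundance
reports and heatmap abundance binning; and a Dirichlet–multinomial
synthetic community generator with planted provenance structure and known
ground truth, so the entire inference is testable without any sequencing
data. It is aimed at microbiome researchers replicating or extending
seed-transmission analyses.

## Worked example

Simulate the 17-species study grid with a seed-detection dropout of 0.3
(seed microbes that transmit but evade detection in the seed itself), run
the filters, and attribute reads:

```r
library(seedprov)

cfg <- generator_config(dropout = 0.3, markers = "16S", rng_seed = 1)
sim <- generate_community(cfg)
tab <- filter_min_reads(sim$tables[["16S"]])$counts
tab <- filter_nontarget(tab, sim$taxonomy)$counts

prov <- provenance_matrix(tab, sim$metadata)
avg <- summarize_provenance(prov)
avg[, 5:8] <- round(avg[, 5:8], 2)
avg[, c("compartment", "substrate", "seed_otu_fraction",
        "seed_read_fraction", "soil_read_fraction")]
#>  compartment substrate seed_otu_fraction seed_read_fraction soil_read_fraction
#>  rhizosphere      sand              0.70               0.61                 NA
#>  rhizosphere      soil              0.14               0.29               0.54
#>         root      sand              0.70               0.60                 NA
#>         root      soil              0.27               0.41               0.32
#>        shoot      sand              0.72               0.64                 NA
#>        shoot      soil              0.45               0.55               0.12

pooled <- pool_replicates(tab, sim$metadata)
core <- core_seed_transmitted_union(to_proportions(pooled$counts), pooled$metadata)
length(core)
#> [1] 8

rec <- evaluate_recovery(prov, tab, sim$metadata, sim$truth)
sprintf("bias %.2f, sign-test p %.1e (n = %d)", rec$bias, rec$sign_test_p, rec$n)
#> [1] "bias -0.32, sign-test p 2.0e-31 (n = 102)"
```

Reading the table: on sterile sand every OTU is in truth seed-derived, yet
only ~61% of reads are seed-attributed — the 30% seed-detection dropout
makes the reference incomplete, so vertical transmission is systematically
*under*estimated (negative bias, confirmed by the sign test). Soil
attribution is undefined on sand by construction. On soil, the soil's read
contribution is largest in the rhizosphere (0.54) and nearly absent in
shoots (0.12), while all 8 planted pan-species core seed OTUs are recovered
in the core seed-transmitted union.

The numbered drivers under `analysis/` run the same workflow as a narrated
sequence — `01_simulate.R` through `05_provenance.R` — writing tables under
`results/`. `run_pipeline()` packages the whole single-marker analysis
(filters → diversity → occupancy → provenance → clustering exports) behind
one configuration object with a JSON run log.

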