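---
title: "Attributing juvenile plant microbiomes to seed or soil: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing juvenile plant microbiomes to seed or soil: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedprov)
```

## The question and the experimental logic

Where does a seedling's microbiome come from? Two candidate sources dominate:
vertical transmission from the seed (its interior and its surface wash, the
spermosphere) and horizontal acquisition from the soil. `seedprov`
implements a deterministic, set-algebraic attribution of each juvenile-plant
OTU -- and of its reads -- to one of those sources, built around a
gnotobiotic design: plants of a multi-species panel are grown in sealed jars
on either sterile sand (seeds are then the only possible inoculum) or field
soil, and rhizosphere, root and shoot communities are profiled alongside the
seeds and spermospheres with 16S (bacteria) and ITS (fungi) amplicons.

Attribution needs no mixture model, because the design itself supplies the
references:

* **Seed (vertical) provenance.** An OTU present in a vegetative sample is
  seed-attributed if it also occurs in the same species' seed or spermosphere
  sample -- the union of the two, since either demonstrates presence on or in
  the seed. For a present set $P$ and reference $R$ the OTU fraction is
  $|P \cap R| / |P|$ and the read fraction is the summed relative abundance
  over $P \cap R$.
* **Soil (horizontal) provenance.** An OTU in a soil-grown sample is
  soil-attributed if it was never observed in any sterile-sand replicate of
  the same species and compartment: $P \setminus S$, with $S$ the union of
  the sand counterparts. The two schemes use different references, so their
  fractions need not (and do not) sum to one; each scheme's unknown
  remainder is reported explicitly.
* **Common / core structure.** An OTU is *common* within a group when its
  occupancy (fraction of samples in which it is present) strictly exceeds
  60% -- on a 17-species panel that means at least 11 of 17, because
  10/17 = 0.588 -- and *core* when occupancy is exactly 100%. Common OTUs of
  soil-grown tissues are classified as seed-derived (also common on sand),
  soil-derived (absent from every sand sample), or neither. Because
  sand-grown plants can only have been colonised from seed, any OTU core to
  a sand-grown compartment is core *and* seed-transmitted; the union of
  those per-compartment core sets is the core seed-transmitted microbiome.

## Processing rules

The pipeline starts from OTU count tables (OTUs binned upstream at 97%
identity) and applies, per marker:

1. **Minimum-read filter**: only OTUs with two or more total raw reads are
   analysed. Applied independently to the 16S and ITS tables, since the two
   loci come from separate amplicon pipelines.
2. **Non-target removal**: OTUs whose lineage or annotations contain a
   blocklist keyword (chloroplast, mitochondria, plant ribosomal, protist;
   case-insensitive substring over lineage + annotations) are removed.
   OTUs with classifier confidence below 0.15 that match no keyword are
   *flagged* for review but retained: a deterministic, auditable stand-in
   for manual curation.
3. **Normalisation**: counts become per-sample relative proportions.
   Zero-total samples are flagged empty, never turned into NaN.

Two replicate-combination schemes are deliberately kept separate, because
they answer different questions:

* **Pooled** (inventories, occupancy, provenance): replicate reads are
  summed, then normalised. Pooling before normalising weights replicates by
  their depth and makes presence a union over replicates -- the right
  behaviour for detection-style questions.
* **Averaged** (community comparison): samples are rarefied to fixed
  per-compartment depths (16S: 3,500 shoot / 3,000 root / 6,500 rhizosphere;
  ITS: 1,000 / 1,000 / 2,000 reads), normalised, then replicate proportion
  vectors are arithmetically averaged. Bray--Curtis dissimilarities and the
  UPGMA sample ordering are computed on these averaged profiles.

Rarefaction is a single multivariate-hypergeometric draw (subsampling reads
without replacement), not an average over repeated draws; samples at or
below the target depth are included unchanged rather than discarded, so a
12-read sample stays in the analysis. The draw is governed by a recorded
`rng_seed` (default 1) in the `rarefaction_policy()`, and samples are
processed in sorted-id order, making the result bit-reproducible and
independent of row order. Seed and spermosphere samples carry no configured
depth and are never rarefied: they are analysed only on the pooled branch.

## Numerical and algorithmic choices

* **Shannon H** uses the natural logarithm (the PAST convention; base is
  configurable) over non-zero proportions; an all-zero profile is undefined
  (NA), not 0.
* **Bray--Curtis** is $1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)$,
  bounded in $[0,1]$, symmetric, zero iff the profiles coincide. The
  triangle inequality is *not* asserted anywhere -- Bray--Curtis does not
  satisfy it.
* **Clustering** is agglomerative with UPGMA (average) linkage by default;
  single and complete linkage are selectable. Exact ties are resolved by
  merging the pair whose clusters carry the lexicographically smallest leaf
  labels, so trees and exported leaf orders are deterministic and invariant
  to input permutation. `stats::hclust` average linkage serves as an
  independent cross-check in the test suite.
* **Presence** defaults to proportion strictly greater than 0 (any read
  after filtering); the threshold is configurable because detection-limit
  sensitivity is an analysis question, not a constant of nature.
* **Abundance bins** for heatmap export are exactly zero, then left-open
  right-closed intervals (0, 0.1%], (0.1, 0.25%], (0.25, 0.5%],
  (0.5, 1%], (1, 5%], (5, 100%].
* **Report ranking** orders OTUs by occupancy, ties by mean abundance, then
  by id -- deterministic regardless of input order.
* Occupancy for seed/spermosphere groups is computed across species (one
  pooled sample per species); for vegetative tissue groups, across species
  within a (compartment, substrate) stratum.

## The synthetic community generator

No raw sequencing data ships with the package; instead
`generate_community()` emits the full design grid with known ground truth,
so every stage -- including the provenance inference itself -- is testable
end to end. Its defaults describe the study conditions: 17 host species,
2 seed + 2 spermosphere replicates, 3 replicates per vegetative compartment
and substrate, two markers.

The planted structure mirrors what the experiment is designed to detect:

* a pool of **core seed OTUs** present in every species' seed and
  spermosphere, carried into every vegetative compartment
  (`carry_over_core = 1`), which is what makes a core seed-transmitted
  union detectable at all;
* **common seed OTUs** with per-OTU species-occupancy targets, always
  including plants at 10/17 and 11/17 to pin the strict >60% boundary from
  both sides;
* **species-specific seed OTUs**, **soil-only OTUs** (zero probability mass
  in sand-grown and seed/spermosphere samples, by construction) and
  **contaminants** whose lineages contain blocklisted keywords, so the
  non-target filter is exercised end to end;
* per-sample communities drawn Dirichlet-multinomial: per-OTU log-normal
  base abundances (`sdlog = 1.5`, heavy-tailed) with label-specific meanlog
  shifts that let seed-transmitted taxa dominate reads, and concentration
  `theta = 25` providing the overdispersion real amplicon data shows;
* log-normal depths (median ~8,000 reads, floor 1,000) with a 2% chance of
  a failed, 12--300-read sample -- exercising the keep-undersampled
  rarefaction rule;
* carry-over rates (0.6 rhizosphere/root, 0.5 shoot) and soil delivery
  probabilities (0.9 rhizosphere, 0.35 root, 0.12 shoot) chosen once to
  reproduce the qualitative field pattern: soil enriches the rhizosphere far
  more than the endosphere or the shoot.

Generation order encodes the causality: seed and spermosphere samples are
drawn first; vegetative communities carry only OTUs actually observed in
that species' seed/spermosphere union. With `ensure_presence = TRUE` and
adequate depth, every community member receives at least one read, so
planted occupancy is realised exactly -- occupancy is the designed variable,
read counts model abundance on top of it.

**Detection dropout** is the generator's model of the hardest real-world
problem in this design: seed microbes that are rare, dormant or resistant to
extraction go undetected in the seed yet appear in the seedling. With
probability `dropout` per observed (species, OTU) seed presence, the OTU's
reads are removed from all of that species' seed/spermosphere samples and
redistributed multinomially over the remaining OTUs (totals keep matching
drawn depths). Transmission still happens from the true presence, so the
seed reference is incomplete -- and seed attribution can only underestimate:
the estimated vertical read fraction is mathematically bounded above by the
truth, which the tests confirm as a strictly negative mean signed error.

What the generator does **not** emulate: sequence-level error (chimeras,
clustering artifacts), compositional correlations between taxa,
plant-genotype-specific filtering of soil taxa, and cross-sample
contamination. Passing tests therefore demonstrate the correctness of the
pipeline's set algebra, filters and statistics under the planted model --
not that real communities satisfy that model.

## Ground truth and scoring

`evaluate_recovery()` compares estimated seed read fractions with the truth
recomputed *on the analysed table*: the read share of OTUs whose planted
label is seed-lineage, within the OTU columns that survived filtering. This
makes the perfect-detection comparison exact (to floating-point roundoff)
regardless of which low-count OTUs the ≥2-read filter removed. Label
accuracy scores `classify_common_provenance()` output against the planted
lineage classes. Under perfect detection (`no_noise_config()`: carry-over
1, dropout 0, no low-depth samples) label accuracy is 100% and the
per-sample vertical read-fraction error is numerically zero; under dropout
0.3 the mean signed error is negative with a one-sided sign-test
p far below 0.01.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance script run the full 17-species
grid (374 samples x ~230 OTUs per marker; both markers in the drivers, 16S
in the acceptance script), 1,000 randomized property fixtures and 500
oracle trials -- sizes chosen so the whole suite completes in well under a
minute on a single CPU while still exercising every rule at the study's
actual design dimensions.

## Known limitations

* Attribution is presence-based set algebra: a taxon present in both seed
  and soil is credited to seed, and the per-scheme unknowns overlap;
  probabilistic source tracking is deliberately out of scope.
* Occupancy at the 60% boundary is sensitive to single-sample detection
  failures on small panels; the strict inequality is the documented,
  pinned behaviour.
* The paper-style workflow rarefies once per sample (single draw); variance
  from the draw is not propagated. The recorded seed makes it reproducible,
  not uncertainty-free.
* Ordination (PCoA/NMDS), PERMANOVA and differential abundance are not
  provided -- the clustering branch exists to order samples for heatmap
  layout, nothing more.
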