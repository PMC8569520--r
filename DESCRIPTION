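Package: seedprov
Title: Seed Versus Soil Provenance Attribution for Juvenile Plant Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to attribute juvenile plant microbiome membership to seed
    (vertical) versus soil (horizontal) provenance from multi-compartment
    amplicon OTU tables. Implements the OTU-level exclusion filters
    (minimum-read and non-target taxonomy blocklist), proportional
    normalization, per-compartment rarefaction, the two replicate-combination
    schemes (pool-then-normalize for inventories, rarefy-normalize-average for
    clustering), Shannon diversity and Bray-Curtis/UPGMA sample ordering,
    occupancy-based common (>60%) and core (100%) microbiome detection,
    set-algebraic seed/soil source attribution across compartments and
    substrates, and a Dirichlet-multinomial synthetic community generator with
    planted transmission structure and known ground truth for validating the
    whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
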