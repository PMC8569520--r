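#' Controlled vocabularies for the experimental design grid
#'
#' Compartments, substrates and marker loci recognised throughout the
#' package. Seed and spermosphere samples are harvested before planting and
#' therefore carry substrate \code{"none"}; the three vegetative compartments
#' (rhizosphere, root, shoot) come from plants grown on either sterile sand
#' or field soil.
#'
#' @name design-vocabulary
#' @aliases COMPARTMENTS VEG_COMPARTMENTS SEED_COMPARTMENTS SUBSTRATES
#'   MARKERS DEFAULT_BLOCKLIST DEFAULT_SPECIES
NULL

#' @rdname design-vocabulary
#' @export
COMPARTMENTS <- c("seed", "spermosphere", "rhizosphere", "root", "shoot")

#' @rdname design-vocabulary
#' @export
VEG_COMPARTMENTS <- c("rhizosphere", "root", "shoot")

#' @rdname design-vocabulary
#' @export
SEED_COMPARTMENTS <- c("seed", "spermosphere")

#' @rdname design-vocabulary
#' @export
SUBSTRATES <- c("none", "sand", "soil")

#' @rdname design-vocabulary
#' @export
MARKERS <- c("16S", "ITS")

#' @rdname design-vocabulary
#' @export
DEFAULT_BLOCKLIST <- c("chloroplast", "mitochondria", "plantae-ribosomal", "protist")

#' @rdname design-vocabulary
#' @export
DEFAULT_SPECIES <- c(
  "maize", "rice", "switchgrass", "brachiaria", "wheat", "sugarcane",
  "barley", "sorghum", "tomato", "coffee", "common_bean", "cassava",
  "soybean", "pea", "sunflower", "arabidopsis", "brachypodium"
)
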