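#' Per-species seed reference sets
#'
#' For each species, the union of OTUs present (proportion above the
#' presence threshold) in that species' pooled seed sample and pooled
#' spermosphere sample -- the "observed in that species' seeds or
#' spermospheres" reference against which vertical (seed) transmission is
#' judged. Species whose seed and spermosphere samples are both empty get an
#' empty reference and are listed in the \code{"empty_species"} attribute.
#'
#' @param props pooled, proportion-normalised table containing the seed and
#'   spermosphere rows.
#' @param meta metadata for those rows.
#' @param presence_threshold presence cutoff.
#' @return named list: species -> character vector of OTU ids.
#' @export
build_seed_reference <- function(props, meta, presence_threshold = 0) {
  props <- as.matrix(props)
  meta <- validate_metadata(meta)
  meta <- meta[match(rownames(props), meta$sample_id), ]
  sel <- meta$compartment %in% SEED_COMPARTMENTS
  props <- props[sel, , drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  species <- sort(unique(meta$species))
  ref <- lapply(species, function(sp) {
    rows <- props[meta$species == sp, , drop = FALSE]
    colnames(rows)[colSums(rows > presence_threshold) > 0]
  })
  names(ref) <- species
  attr(ref, "empty_species") <- species[lengths(ref) == 0]
  ref
}

#' Sterile-sand counterpart sets
#'
#' For each (species, compartment), the union of OTUs observed across all
#' sterile-sand replicates of that species and compartment. Union, never
#' intersection: an OTU seen in any sand replicate counts as sand-observed.
#'
#' @param counts samples x OTUs table (counts or proportions; presence only
#'   is used).
#' @param meta metadata for the rows.
#' @param presence_threshold presence cutoff.
#' @return named list keyed \code{"species|compartment"} -> OTU id vector.
#' @export
sand_counterparts <- function(counts, meta, presence_threshold = 0) {
  counts <- as.matrix(counts)
  meta <- validate_metadata(meta)
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  sel <- meta$substrate == "sand"
  counts <- counts[sel, , drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  key <- paste(meta$species, meta$compartment, sep = "|")
  out <- lapply(sort(unique(key)), function(k) {
    rows <- counts[key == k, , drop = FALSE]
    colnames(rows)[colSums(rows > presence_threshold) > 0]
  })
  names(out) <- sort(unique(key))
  out
}

#' Attribute a sample's OTUs and reads to its seed reference
#'
#' Of the OTUs present in the sample, the fraction that also occur in the
#' species' seed/spermosphere reference set, and the fraction of the
#' sample's reads those OTUs carry.
#'
#' @param p named proportion vector for one sample.
#' @param ref character vector of reference OTU ids.
#' @param presence_threshold presence cutoff.
#' @return list with otu_fraction, read_fraction, n_present and
#'   attributed_otus; fractions are NA (flagged undefined) for an empty
#'   sample.
#' @export
seed_attribution <- function(p, ref, presence_threshold = 0) {
  present <- names(p)[p > presence_threshold]
  if (!length(present)) {
    return(list(otu_fraction = NA_real_, read_fraction = NA_real_,
                n_present = 0L, attributed_otus = character(0)))
  }
  hit <- intersect(present, ref)
  list(otu_fraction = length(hit) / length(present),
       read_fraction = sum(p[hit]),
       n_present = length(present),
       attributed_otus = hit)
}

#' Attribute a soil-grown sample's OTUs and reads to soil
#'
#' Subtractive attribution: OTUs present in the soil-grown sample but never
#' observed in the matching sterile-sand counterpart (same species, same
#' compartment) are attributed to soil. Fractions as in
#' [seed_attribution()].
#'
#' @param p named proportion vector for one soil-grown sample.
#' @param sand_set the species/compartment sand counterpart OTU set.
#' @param presence_threshold presence cutoff.
#' @return list with otu_fraction, read_fraction, n_present and
#'   attributed_otus.
#' @export
soil_attribution <- function(p, sand_set, presence_threshold = 0) {
  present <- names(p)[p > presence_threshold]
  if (!length(present)) {
    return(list(otu_fraction = NA_real_, read_fraction = NA_real_,
                n_present = 0L, attributed_otus = character(0)))
  }
  hit <- setdiff(present, sand_set)
  list(otu_fraction = length(hit) / length(present),
       read_fraction = sum(p[hit]),
       n_present = length(present),
       attributed_otus = hit)
}

#' Classify common OTUs of a compartment by provenance
#'
#' Within one vegetative compartment, OTUs common among soil-grown samples
#' (occupancy strictly above the threshold) are labelled:
#' \describe{
#'   \item{seed}{also common among sterile-sand-grown samples (sand occupancy
#'     above the threshold) -- presence without soil demonstrates seed
#'     provenance;}
#'   \item{soil}{absent from every sand-grown sample of the compartment;}
#'   \item{neither}{all remaining cases, including sand occupancy above zero
#'     but at or below the threshold.}
#' }
#'
#' @param soil_occ [occupancy()] over the compartment's soil-grown samples.
#' @param sand_occ [occupancy()] over the matching sand-grown samples
#'   (same species panel).
#' @param threshold commonness threshold (strict inequality).
#' @return data.frame with columns otu_id, label, soil_occupancy,
#'   sand_occupancy; one row per common (soil) OTU.
#' @export
classify_common_provenance <- function(soil_occ, sand_occ, threshold = 0.6) {
  common <- soil_occ[soil_occ$occupancy > threshold, , drop = FALSE]
  sand_map <- sand_occ$occupancy[match(common$otu_id, sand_occ$otu_id)]
  sand_map[is.na(sand_map)] <- 0
  label <- ifelse(sand_map > threshold, "seed",
                  ifelse(sand_map == 0, "soil", "neither"))
  data.frame(otu_id = common$otu_id, label = label,
             soil_occupancy = common$occupancy, sand_occupancy = sand_map,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core seed-transmitted union across sand-grown compartments
#'
#' OTUs with 100% occupancy across all species in at least one sand-grown
#' vegetative compartment (rhizosphere, root or shoot). Because sand-grown
#' plants can only have received microbes from their seeds, membership in any
#' of these per-compartment core sets demonstrates core, seed-transmitted
#' status; the result is their union.
#'
#' @param props pooled, normalised table of sand-grown vegetative samples
#'   (one row per species x compartment).
#' @param meta metadata for the rows.
#' @param presence_threshold presence cutoff.
#' @return character vector of OTU ids; per-compartment core sets in the
#'   \code{"per_compartment"} attribute.
#' @export
core_seed_transmitted_union <- function(props, meta, presence_threshold = 0) {
  props <- as.matrix(props)
  meta <- validate_metadata(meta)
  meta <- meta[match(rownames(props), meta$sample_id), ]
  sel <- meta$substrate == "sand" & meta$compartment %in% VEG_COMPARTMENTS
  props <- props[sel, , drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  per <- lapply(VEG_COMPARTMENTS, function(cpt) {
    rows <- meta$compartment == cpt
    if (!any(rows)) return(character(0))
    core_otus(occupancy(props, rows, presence_threshold))
  })
  names(per) <- VEG_COMPARTMENTS
  out <- sort(unique(unlist(per)))
  attr(out, "per_compartment") <- per
  out
}

#' Full seed/soil provenance summary across the design grid
#'
#' Orchestrates the source attribution for one marker: builds per-species
#' seed references from the pooled seed/spermosphere samples, sand
#' counterpart sets per (species, compartment), then attributes every
#' vegetative sample's OTUs and reads to seed (all substrates) and to soil
#' (soil-grown samples only; soil attribution is undefined by construction on
#' sand). Replicates are pooled by default; \code{replicate_mode =
#' "per_rep"} attributes each replicate separately for uncertainty
#' inspection. The seed and soil schemes use different references, so their
#' fractions need not sum to 1; the per-scheme unknown remainder is reported
#' explicitly.
#'
#' @param counts filtered samples x OTUs count table (single marker).
#' @param meta metadata covering the table.
#' @param presence_threshold presence cutoff.
#' @param replicate_mode \code{"pooled"} or \code{"per_rep"}.
#' @param allow_missing tolerate missing strata (flag rows instead of
#'   erroring when a species lacks seed/spermosphere samples or a soil-grown
#'   stratum lacks its sand counterpart).
#' @return data.frame with one row per (species, compartment, substrate
#'   \[, replicate\]): seed_otu_fraction, seed_read_fraction,
#'   seed_unknown_otu_fraction, seed_unknown_read_fraction,
#'   soil_otu_fraction, soil_read_fraction (NA on sand), n_present and a
#'   flag column; column-block averages over species via
#'   [summarize_provenance()].
#' @export
provenance_matrix <- function(counts, meta, presence_threshold = 0,
                              replicate_mode = c("pooled", "per_rep"),
                              allow_missing = TRUE) {
  replicate_mode <- match.arg(replicate_mode)
  counts <- otu_table(counts)
  meta <- validate_metadata(meta, counts)
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  if (length(unique(meta$marker)) != 1L) {
    stop("provenance_matrix expects a single marker; got: ",
         paste(unique(meta$marker), collapse = ", "))
  }
  # seed references always come from pooled seed/spermosphere tables
  pooled <- pool_replicates(counts, meta)
  pooled_props <- to_proportions(pooled$counts)
  refs <- build_seed_reference(pooled_props, pooled$metadata, presence_threshold)
  sand_sets <- sand_counterparts(counts, meta, presence_threshold)

  if (replicate_mode == "pooled") {
    tab <- pooled_props
    tmeta <- pooled$metadata
    tmeta$replicate <- NA_integer_
  } else {
    tab <- to_proportions(counts)
    tmeta <- meta
  }
  veg <- tmeta$compartment %in% VEG_COMPARTMENTS
  tab <- tab[veg, , drop = FALSE]
  tmeta <- tmeta[veg, , drop = FALSE]

  rows <- lapply(seq_len(nrow(tmeta)), function(i) {
    sp <- tmeta$species[i]; cpt <- tmeta$compartment[i]
    sub <- tmeta$substrate[i]
    p <- tab[i, ]
    flag <- character(0)
    if (!sp %in% names(refs)) {
      if (!allow_missing) stop("no seed/spermosphere reference for species ", sp)
      flag <- c(flag, "missing_seed_reference")
      sa <- list(otu_fraction = NA_real_, read_fraction = NA_real_, n_present = NA_integer_)
    } else {
      sa <- seed_attribution(p, refs[[sp]], presence_threshold)
      if (sp %in% attr(refs, "empty_species")) flag <- c(flag, "empty_seed_reference")
    }
    so <- list(otu_fraction = NA_real_, read_fraction = NA_real_)
    if (sub == "soil") {
      k <- paste(sp, cpt, sep = "|")
      if (!k %in% names(sand_sets)) {
        if (!allow_missing) stop("no sterile-sand counterpart for stratum ", k)
        flag <- c(flag, "missing_sand_counterpart")
      } else {
        so <- soil_attribution(p, sand_sets[[k]], presence_threshold)
      }
    }
    if (identical(sa$n_present, 0L)) flag <- c(flag, "empty_sample")
    data.frame(
      species = sp, compartment = cpt, substrate = sub,
      marker = tmeta$marker[i], replicate = tmeta$replicate[i],
      n_present = if (is.null(sa$n_present)) NA_integer_ else sa$n_present,
      seed_otu_fraction = sa$otu_fraction,
      seed_read_fraction = sa$read_fraction,
      seed_unknown_otu_fraction = 1 - sa$otu_fraction,
      seed_unknown_read_fraction = 1 - sa$read_fraction,
      soil_otu_fraction = so$otu_fraction,
      soil_read_fraction = so$read_fraction,
      flag = paste(flag, collapse = ";"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$compartment, out$substrate, out$species), , drop = FALSE]
}

#' Column-block averages of a provenance summary
#'
#' Mean fractions across species per (compartment, substrate, marker), the
#' footer row of each attribution column block. Averages are taken over the
#' available (non-flagged-missing, non-NA) rows.
#'
#' @param summary a [provenance_matrix()] result.
#' @return data.frame of per-stratum means with an n_species column.
#' @export
summarize_provenance <- function(summary) {
  key <- paste(summary$compartment, summary$substrate, summary$marker, sep = "|")
  num_cols <- c("seed_otu_fraction", "seed_read_fraction",
                "soil_otu_fraction", "soil_read_fraction")
  out <- do.call(rbind, lapply(sort(unique(key)), function(k) {
    rows <- summary[key == k, , drop = FALSE]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    means <- vapply(num_cols, function(cl) mean(rows[[cl]], na.rm = TRUE), 0)
    means[is.nan(means)] <- NA_real_
    data.frame(compartment = parts[1L], substrate = parts[2L], marker = parts[3L],
               n_species = length(unique(rows$species)),
               as.list(means), stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}
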