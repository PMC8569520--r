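#' Configuration for the synthetic community generator
#'
#' Describes the planted study design the generator emulates: a panel of host
#' species, each contributing seed and spermosphere samples (substrate
#' \code{none}) plus rhizosphere/root/shoot samples on sterile sand and on
#' field soil; two marker loci; and OTU pools with known provenance --
#' core seed OTUs present in every species' seed pool, common seed OTUs with
#' per-OTU species-occupancy targets straddling the 60% commonness boundary,
#' species-specific seed OTUs, soil-only OTUs that never occur in sand-grown
#' or seed/spermosphere samples, and non-target contaminant OTUs carrying
#' blocklisted (chloroplast/mitochondria-style) lineages. Abundances follow a
#' Dirichlet-multinomial with heavy-tailed (log-normal) per-OTU base
#' abundances; sequencing depths are log-normal with an occasional very-low-
#' depth sample; seed-reference detection dropout \code{dropout} masks each
#' observed seed presence independently, mimicking undetected seed microbes.
#'
#' @param n_species number of host species (default 17).
#' @param species species names (default: the 17-crop panel).
#' @param reps_seed replicates per seed and per spermosphere sample (2).
#' @param reps_veg replicates per vegetative compartment x substrate (3).
#' @param markers marker loci to simulate.
#' @param n_core_seed,n_common_seed,n_species_seed,n_soil_only,n_contaminant
#'   OTU pool sizes (\code{n_species_seed} is per species).
#' @param common_occupancy_targets integer vector (length
#'   \code{n_common_seed}) of species counts each common seed OTU occupies;
#'   NULL draws them, always planting at least two OTUs just below and two
#'   just above the 60% boundary.
#' @param base_meanlog,base_sdlog log-normal base-abundance parameters.
#' @param label_meanlog_shift named meanlog shifts per provenance label,
#'   letting seed-transmitted OTUs dominate read abundance as in real
#'   juvenile plant microbiomes.
#' @param theta Dirichlet concentration (smaller = more overdispersion).
#' @param carry_over per-compartment probability that an observed seed OTU is
#'   carried into that vegetative compartment.
#' @param carry_over_core per-compartment carry-over for core seed OTUs;
#'   defaults to 1 so the planted pan-species core is transmitted to every
#'   compartment of every host, the structure that makes a core
#'   seed-transmitted union detectable.
#' @param soil_compartment_prob per-compartment probability that a soil-pool
#'   OTU assigned to a species reaches that compartment (soil mostly enriches
#'   the rhizosphere).
#' @param contaminant_sample_prob per-compartment probability that a
#'   contaminant OTU appears in a given sample.
#' @param dropout seed-reference detection dropout probability in \[0, 1).
#' @param depth_meanlog,depth_sdlog,depth_min sequencing-depth model.
#' @param low_depth_prob,low_depth_range probability and range of failed,
#'   very-low-depth samples.
#' @param ensure_presence when depth allows, give every community member at
#'   least one read so planted occupancy is realised exactly.
#' @param rng_seed integer seed; a fixed seed gives byte-identical output.
#' @return validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_species = 17L,
                             species = NULL,
                             reps_seed = 2L,
                             reps_veg = 3L,
                             markers = c("16S", "ITS"),
                             n_core_seed = 8L,
                             n_common_seed = 24L,
                             n_species_seed = 3L,
                             n_soil_only = 140L,
                             n_contaminant = 10L,
                             common_occupancy_targets = NULL,
                             base_meanlog = 0,
                             base_sdlog = 1.5,
                             label_meanlog_shift = c(core_seed = 2, common_seed = 1,
                                                     species_seed = 0.5, soil_only = 0,
                                                     contaminant = 0.5),
                             theta = 25,
                             carry_over = c(rhizosphere = 0.6, root = 0.6, shoot = 0.5),
                             carry_over_core = c(rhizosphere = 1, root = 1, shoot = 1),
                             soil_compartment_prob = c(rhizosphere = 0.9, root = 0.35,
                                                       shoot = 0.12),
                             contaminant_sample_prob = c(seed = 0.8, spermosphere = 0.6,
                                                         rhizosphere = 0.3, root = 0.3,
                                                         shoot = 0.5),
                             dropout = 0,
                             depth_meanlog = log(8000),
                             depth_sdlog = 0.6,
                             depth_min = 1000L,
                             low_depth_prob = 0.02,
                             low_depth_range = c(12L, 300L),
                             ensure_presence = TRUE,
                             rng_seed = 1L) {
  if (is.null(species)) {
    species <- if (n_species <= length(DEFAULT_SPECIES)) {
      DEFAULT_SPECIES[seq_len(n_species)]
    } else {
      c(DEFAULT_SPECIES,
        paste0("species", seq_len(n_species - length(DEFAULT_SPECIES))))
    }
  }
  if (length(species) != n_species) stop("species must have length n_species")
  pools <- c(n_core_seed, n_common_seed, n_species_seed, n_soil_only, n_contaminant)
  if (any(pools < 0)) stop("pool sizes must be >= 0")
  if (sum(pools) == 0) stop("infeasible config: no OTUs at all")
  probs <- c(carry_over, carry_over_core, soil_compartment_prob,
             contaminant_sample_prob, dropout, low_depth_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dropout >= 1) stop("dropout must be < 1")
  if (!all(VEG_COMPARTMENTS %in% names(carry_over))) {
    stop("carry_over needs entries for ", paste(VEG_COMPARTMENTS, collapse = ", "))
  }
  if (!is.null(common_occupancy_targets)) {
    if (length(common_occupancy_targets) != n_common_seed ||
        any(common_occupancy_targets < 1 | common_occupancy_targets > n_species)) {
      stop("common_occupancy_targets must be n_common_seed counts in [1, n_species]")
    }
  }
  structure(list(
    n_species = as.integer(n_species), species = species,
    reps_seed = as.integer(reps_seed), reps_veg = as.integer(reps_veg),
    markers = markers,
    n_core_seed = as.integer(n_core_seed), n_common_seed = as.integer(n_common_seed),
    n_species_seed = as.integer(n_species_seed), n_soil_only = as.integer(n_soil_only),
    n_contaminant = as.integer(n_contaminant),
    common_occupancy_targets = common_occupancy_targets,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    label_meanlog_shift = label_meanlog_shift, theta = theta,
    carry_over = carry_over, carry_over_core = carry_over_core,
    soil_compartment_prob = soil_compartment_prob,
    contaminant_sample_prob = contaminant_sample_prob,
    dropout = dropout,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    depth_min = as.integer(depth_min),
    low_depth_prob = low_depth_prob,
    low_depth_range = as.integer(low_depth_range),
    ensure_presence = isTRUE(ensure_presence),
    rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
}

#' Perfect-detection variant of a generator configuration
#'
#' Carry-over and soil compartment delivery set to 1, no dropout, no
#' low-depth samples and depths always large enough to realise every planted
#' presence -- the regime in which the set-algebraic provenance rules must
#' recover every planted label exactly.
#'
#' @param ... arguments passed on to [generator_config()].
#' @return a \code{generator_config}.
#' @export
no_noise_config <- function(...) {
  cfg <- generator_config(...)
  cfg$carry_over[] <- 1
  cfg$carry_over_core[] <- 1
  cfg$soil_compartment_prob[] <- 1
  cfg$dropout <- 0
  cfg$low_depth_prob <- 0
  cfg$depth_min <- max(cfg$depth_min, 4000L)
  cfg$ensure_presence <- TRUE
  cfg
}

# genus/phylum pools used to fabricate plausible lineages
.genus_pools <- list(
  "16S" = list(
    seed = c(Pantoea = "Proteobacteria", Enterobacter = "Proteobacteria",
             Pseudomonas = "Proteobacteria", Bacillus = "Firmicutes",
             Klebsiella = "Proteobacteria", Massilia = "Proteobacteria",
             Acidovorax = "Proteobacteria", Stenotrophomonas = "Proteobacteria",
             Rhizobium = "Proteobacteria", Methylobacterium = "Proteobacteria",
             Serratia = "Proteobacteria", Telluria = "Proteobacteria"),
    soil = c(Streptomyces = "Actinobacteria", Arthrobacter = "Actinobacteria",
             Flavobacterium = "Bacteroidetes", Sphingomonas = "Proteobacteria",
             Nitrospira = "Nitrospirae", Bradyrhizobium = "Proteobacteria",
             Gemmatimonas = "Gemmatimonadetes", Bacteroides = "Bacteroidetes"),
    contaminant = c("d__Bacteria; p__Cyanobacteria; c__Chloroplast; g__Chloroplast",
                    "d__Plantae; p__Streptophyta; g__Mitochondria")
  ),
  "ITS" = list(
    seed = c(Fusarium = "Ascomycota", Alternaria = "Ascomycota",
             Pseudozyma = "Basidiomycota", Sarocladium = "Ascomycota",
             Penicillium = "Ascomycota", Phoma = "Ascomycota"),
    soil = c(Mortierella = "Mortierellomycota", Trichoderma = "Ascomycota",
             Aspergillus = "Ascomycota", Rhizoctonia = "Basidiomycota",
             Chaetomium = "Ascomycota", Cryptococcus = "Basidiomycota"),
    contaminant = c("d__Plantae; p__Streptophyta; g__Plantae-ribosomal",
                    "d__Eukaryota; p__Cercozoa; g__Protist")
  )
)

.vertical_labels <- c("core_seed", "common_seed", "species_seed")

draw_depth <- function(cfg) {
  if (stats::runif(1) < cfg$low_depth_prob) {
    return(sample(seq(cfg$low_depth_range[1L], cfg$low_depth_range[2L]), 1L))
  }
  max(cfg$depth_min, as.integer(round(stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog))))
}

# Dirichlet-multinomial counts for one sample; `members` indexes the OTUs
# present in the sample's source community
sample_counts <- function(members, base, theta, depth, ensure, n_otu) {
  counts <- integer(n_otu)
  k <- length(members)
  if (k == 0L || depth == 0L) return(counts)
  b <- base[members]
  alpha <- theta * b / sum(b)
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  p <- g / sum(g)
  if (ensure && depth >= k) {
    counts[members] <- 1L + as.integer(stats::rmultinom(1L, depth - k, p))
  } else {
    counts[members] <- as.integer(stats::rmultinom(1L, depth, p))
  }
  counts
}

generate_marker <- function(cfg, marker) {
  prefix <- if (marker == "16S") "Bact" else "Fung"
  nsp <- cfg$n_species
  sp <- cfg$species
  n_spp_total <- cfg$n_species_seed * nsp
  label <- c(rep("core_seed", cfg$n_core_seed),
             rep("common_seed", cfg$n_common_seed),
             rep("species_seed", n_spp_total),
             rep("soil_only", cfg$n_soil_only),
             rep("contaminant", cfg$n_contaminant))
  n_otu <- length(label)
  otu_id <- paste0(prefix, "OTU", seq_len(n_otu))

  base <- stats::rlnorm(n_otu, cfg$base_meanlog + cfg$label_meanlog_shift[label],
                        cfg$base_sdlog)

  # taxonomy
  pools <- .genus_pools[[marker]]
  lineage <- character(n_otu)
  dom <- if (marker == "16S") "d__Bacteria" else "d__Fungi"
  for (i in seq_len(n_otu)) {
    if (label[i] == "contaminant") {
      lineage[i] <- sample(pools$contaminant, 1L)
    } else {
      pool <- if (label[i] == "soil_only") pools$soil else pools$seed
      g <- sample(names(pool), 1L)
      lineage[i] <- paste0(dom, "; p__", pool[[g]], "; g__", g)
    }
  }
  confidence <- stats::runif(n_otu, 0.85, 1)
  target <- which(label != "contaminant")
  low_id <- sample(target, min(2L, length(target)))
  confidence[low_id] <- stats::runif(length(low_id), 0.05, 0.12)
  tax <- data.frame(otu_id = otu_id, lineage = lineage, confidence = confidence,
                    annotations = "", marker = marker, stringsAsFactors = FALSE)

  # membership design
  seed_member <- sperm_member <- soil_member <- matrix(FALSE, n_otu, nsp,
                                                       dimnames = list(otu_id, sp))
  idx_core <- which(label == "core_seed")
  idx_common <- which(label == "common_seed")
  idx_spp <- which(label == "species_seed")
  idx_soil <- which(label == "soil_only")
  idx_cont <- which(label == "contaminant")

  seed_member[idx_core, ] <- TRUE
  sperm_member[idx_core, ] <- TRUE

  boundary <- floor(0.6 * nsp)          # just-below-common species count
  targets <- cfg$common_occupancy_targets
  if (is.null(targets) && length(idx_common)) {
    targets <- sample(seq(max(2L, boundary - 3L), nsp), length(idx_common),
                      replace = TRUE)
    # always pin the strict-inequality boundary from both sides
    pin <- rep(c(boundary, boundary + 1L), length.out = min(4L, length(targets)))
    targets[seq_along(pin)] <- pin
  }
  occupancy_target <- rep(NA_integer_, n_otu)
  occupancy_target[idx_common] <- targets
  for (j in seq_along(idx_common)) {
    who <- sample(nsp, targets[j])
    habitat <- sample(c("both", "spermosphere", "seed"), 1L, prob = c(0.4, 0.4, 0.2))
    if (habitat %in% c("both", "seed")) seed_member[idx_common[j], who] <- TRUE
    if (habitat %in% c("both", "spermosphere")) sperm_member[idx_common[j], who] <- TRUE
  }
  if (length(idx_spp)) {
    host <- rep(seq_len(nsp), each = cfg$n_species_seed)
    for (j in seq_along(idx_spp)) {
      habitat <- sample(c("seed", "both"), 1L, prob = c(0.7, 0.3))
      seed_member[idx_spp[j], host[j]] <- TRUE
      if (habitat == "both") sperm_member[idx_spp[j], host[j]] <- TRUE
    }
  }
  soil_target <- rep(NA_integer_, n_otu)
  if (length(idx_soil)) {
    soil_target[idx_soil] <- sample(seq(max(2L, floor(0.35 * nsp)), nsp),
                                    length(idx_soil), replace = TRUE)
    for (j in idx_soil) soil_member[j, sample(nsp, soil_target[j])] <- TRUE
  }

  vertical <- label %in% .vertical_labels

  samples <- list()   # sample_id -> counts
  meta_rows <- list()
  masked_rows <- list()
  add_sample <- function(sid, species_i, cpt, substrate, rep_i, counts) {
    samples[[sid]] <<- counts
    meta_rows[[sid]] <<- data.frame(
      sample_id = sid, species = sp[species_i], compartment = cpt,
      substrate = substrate, replicate = rep_i, marker = marker,
      stringsAsFactors = FALSE)
  }

  s_obs <- vector("list", nsp)    # observed seed-reference sets (pre-dropout)
  for (i in seq_len(nsp)) {
    seed_ids <- character(0)
    for (cpt in SEED_COMPARTMENTS) {
      member_base <- if (cpt == "seed") seed_member[, i] else sperm_member[, i]
      for (r in seq_len(cfg$reps_seed)) {
        members <- which(member_base |
                           (label == "contaminant" &
                              stats::runif(n_otu) < cfg$contaminant_sample_prob[[cpt]]))
        if (!length(members)) members <- idx_cont[1L]
        depth <- draw_depth(cfg)
        cnt <- sample_counts(members, base, cfg$theta, depth,
                             cfg$ensure_presence, n_otu)
        sid <- paste(sp[i], cpt, "none", r, marker, sep = "_")
        add_sample(sid, i, cpt, "none", r, cnt)
        seed_ids <- c(seed_ids, sid)
      }
    }
    obs <- rep(FALSE, n_otu)
    for (sid in seed_ids) obs <- obs | (samples[[sid]] > 0L)
    s_obs[[i]] <- which(obs & vertical)

    # detection dropout: mask observed seed-reference presences, keeping depths
    if (cfg$dropout > 0 && length(s_obs[[i]])) {
      masked <- s_obs[[i]][stats::runif(length(s_obs[[i]])) < cfg$dropout]
      if (length(masked)) {
        masked_rows[[length(masked_rows) + 1L]] <- data.frame(
          species = sp[i], otu_id = otu_id[masked], marker = marker,
          stringsAsFactors = FALSE)
        for (sid in seed_ids) {
          cnt <- samples[[sid]]
          r <- sum(cnt[masked])
          if (r == 0L) next
          cnt[masked] <- 0L
          rest <- which(cnt > 0L)
          if (length(rest)) {
            cnt[rest] <- cnt[rest] +
              as.integer(stats::rmultinom(1L, r, cnt[rest] / sum(cnt[rest])))
          } else {
            next  # nothing left to absorb the reads; leave sample untouched
          }
          samples[[sid]] <- cnt
        }
      }
    }

    # vegetative compartments: carried seed OTUs + (on soil) soil pool
    for (cpt in VEG_COMPARTMENTS) {
      p_carry <- ifelse(label[s_obs[[i]]] == "core_seed",
                        cfg$carry_over_core[[cpt]], cfg$carry_over[[cpt]])
      carried <- s_obs[[i]][stats::runif(length(s_obs[[i]])) < p_carry]
      soil_set <- idx_soil[soil_member[idx_soil, i] &
                             stats::runif(length(idx_soil)) < cfg$soil_compartment_prob[[cpt]]]
      for (substrate in c("sand", "soil")) {
        comm_fixed <- if (substrate == "soil") union(carried, soil_set) else carried
        for (r in seq_len(cfg$reps_veg)) {
          members <- union(comm_fixed,
                           idx_cont[stats::runif(length(idx_cont)) <
                                      cfg$contaminant_sample_prob[[cpt]]])
          if (!length(members)) members <- idx_cont[1L]
          depth <- draw_depth(cfg)
          cnt <- sample_counts(sort(members), base, cfg$theta, depth,
                               cfg$ensure_presence, n_otu)
          sid <- paste(sp[i], cpt, substrate, r, marker, sep = "_")
          add_sample(sid, i, cpt, substrate, r, cnt)
        }
      }
    }
  }

  counts <- do.call(rbind, samples)
  rownames(counts) <- names(samples)
  colnames(counts) <- otu_id
  storage.mode(counts) <- "integer"
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL

  # per-sample ground truth on the raw counts (contaminant reads set aside,
  # matching the analysed denominator after non-target filtering)
  veg_rows <- meta$compartment %in% VEG_COMPARTMENTS
  vert_reads <- counts[, vertical, drop = FALSE]
  soil_reads <- counts[, label == "soil_only", drop = FALSE]
  cont_reads <- counts[, label == "contaminant", drop = FALSE]
  target_total <- rowSums(vert_reads) + rowSums(soil_reads)
  truth_samples <- data.frame(
    meta,
    total_reads = rowSums(counts),
    contaminant_reads = rowSums(cont_reads),
    true_vertical_read_fraction = ifelse(target_total > 0,
                                         rowSums(vert_reads) / target_total, NA_real_),
    true_soil_read_fraction = ifelse(target_total > 0,
                                     rowSums(soil_reads) / target_total, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  truth_samples$true_vertical_read_fraction[!veg_rows] <- NA_real_
  truth_samples$true_soil_read_fraction[!veg_rows] <- NA_real_

  otu_labels <- data.frame(otu_id = otu_id, marker = marker, label = label,
                           occupancy_target = occupancy_target,
                           soil_species_target = soil_target,
                           stringsAsFactors = FALSE)
  list(counts = otu_table(counts), taxonomy = tax, metadata = meta,
       otu_labels = otu_labels, sample_truth = truth_samples,
       masked = if (length(masked_rows)) do.call(rbind, masked_rows) else
         data.frame(species = character(0), otu_id = character(0),
                    marker = character(0), stringsAsFactors = FALSE))
}

#' Generate a synthetic multi-compartment community with known ground truth
#'
#' Emits one OTU count table per marker over the full design grid, the shared
#' sample metadata and taxonomy tables, and the ground truth: per-OTU planted
#' provenance labels and per-sample true vertical/soil read fractions
#' (computed on the generated counts with contaminant reads set aside). With
#' \code{dropout = 0} and \code{ensure_presence}, every vertically
#' transmitted OTU present in a species' vegetative samples is present in
#' that species' observed seed/spermosphere union by construction; soil-only
#' OTUs never occur in sand-grown or seed/spermosphere samples. A fixed
#' \code{rng_seed} gives byte-identical output.
#'
#' @param config a [generator_config()].
#' @return list with \code{tables} (named list of samples x OTUs matrices,
#'   one per marker), \code{metadata}, \code{taxonomy}, \code{truth} (list:
#'   \code{otu_labels}, \code{sample_truth}, \code{masked}) and the echoed
#'   \code{config}.
#' @export
generate_community <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) stop("config must be a generator_config")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)
  per <- lapply(config$markers, function(m) generate_marker(config, m))
  names(per) <- config$markers
  list(
    tables = lapply(per, `[[`, "counts"),
    metadata = do.call(rbind, lapply(per, `[[`, "metadata")),
    taxonomy = do.call(rbind, c(lapply(per, `[[`, "taxonomy"),
                                list(make.row.names = FALSE))),
    truth = list(
      otu_labels = do.call(rbind, c(lapply(per, `[[`, "otu_labels"),
                                    list(make.row.names = FALSE))),
      sample_truth = do.call(rbind, c(lapply(per, `[[`, "sample_truth"),
                                      list(make.row.names = FALSE))),
      masked = do.call(rbind, c(lapply(per, `[[`, "masked"),
                                list(make.row.names = FALSE)))
    ),
    config = config
  )
}

#' Score pipeline output against generator ground truth
#'
#' Compares estimated seed (vertical) read fractions from a
#' [provenance_matrix()] summary with the true fractions recomputed on the
#' analysed table itself: for every summary row, the true vertical fraction
#' is the read share of OTUs whose planted label is seed-lineage among all
#' reads of the constituent samples, restricted to the OTU columns actually
#' analysed. (Computing truth on the analysed table makes the comparison
#' exact under perfect detection, independent of which OTUs the read-count
#' filters removed.) Optionally scores a [classify_common_provenance()]
#' labelling against the planted lineage classes.
#'
#' @param summary a [provenance_matrix()] result.
#' @param counts the filtered table the summary was computed from.
#' @param meta metadata covering \code{counts}.
#' @param truth the generator's \code{truth} list.
#' @param classification optional classification data.frame (otu_id, label).
#' @return list: \code{per_sample} (estimate, truth, signed error per row),
#'   \code{bias}, \code{rmse}, \code{n}, \code{sign_test_p} (one-sided
#'   binomial test for systematic underestimation), and -- when
#'   \code{classification} is given -- \code{label_accuracy} and
#'   \code{confusion}.
#' @export
evaluate_recovery <- function(summary, counts, meta, truth, classification = NULL) {
  counts <- as.matrix(counts)
  meta <- validate_metadata(meta)
  labels <- truth$otu_labels
  lab <- labels$label[match(colnames(counts), labels$otu_id)]
  if (anyNA(lab)) stop("analysed OTUs missing from ground truth: ",
                       paste(colnames(counts)[is.na(lab)], collapse = ", "))
  vert_cols <- lab %in% .vertical_labels

  per <- summary
  per$true_vertical_read_fraction <- NA_real_
  for (i in seq_len(nrow(per))) {
    sel <- meta$species == per$species[i] &
      meta$compartment == per$compartment[i] &
      meta$substrate == per$substrate[i] &
      meta$marker == per$marker[i]
    if (!is.na(per$replicate[i])) sel <- sel & meta$replicate == per$replicate[i]
    ids <- intersect(meta$sample_id[sel], rownames(counts))
    if (!length(ids)) next
    tot <- sum(counts[ids, , drop = FALSE])
    if (tot == 0) next
    per$true_vertical_read_fraction[i] <-
      sum(counts[ids, vert_cols, drop = FALSE]) / tot
  }
  per$signed_error <- per$seed_read_fraction - per$true_vertical_read_fraction
  e <- per$signed_error[!is.na(per$signed_error)]
  nz <- e[e != 0]
  sign_p <- if (length(nz)) {
    stats::binom.test(sum(nz < 0), length(nz), p = 0.5,
                      alternative = "greater")$p.value
  } else 1
  out <- list(per_sample = per,
              bias = mean(e),
              rmse = sqrt(mean(e^2)),
              n = length(e),
              sign_test_p = sign_p)
  if (!is.null(classification)) {
    mapped <- c(core_seed = "seed", common_seed = "seed", species_seed = "seed",
                soil_only = "soil", contaminant = "contaminant")
    true_lab <- mapped[labels$label[match(classification$otu_id, labels$otu_id)]]
    scored <- classification$label %in% c("seed", "soil")
    out$label_accuracy <- if (any(scored)) {
      mean(classification$label[scored] == true_lab[scored])
    } else NA_real_
    out$confusion <- table(predicted = classification$label, truth = true_lab)
  }
  out
}
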