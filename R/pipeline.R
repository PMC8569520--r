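#' Run configuration for the full analysis pipeline
#'
#' Collects every input and tunable of a single-marker pipeline run. Inputs
#' may be given as file paths (TSV/BIOM via the readers) or as in-memory
#' objects. Unknown arguments are rejected up front, and the whole
#' configuration is echoed verbatim into the JSON run log.
#'
#' @param counts samples x OTUs count matrix, or path to a TSV/BIOM table.
#' @param metadata metadata data.frame or path.
#' @param taxonomy taxonomy data.frame or path.
#' @param marker marker this run analyses (one of 16S, ITS).
#' @param out_dir output directory (created if needed).
#' @param min_reads minimum total reads per OTU.
#' @param blocklist non-target lineage keywords.
#' @param identity_floor confidence below which unmatched OTUs are flagged.
#' @param presence_threshold proportion above which an OTU counts as present.
#' @param common_threshold occupancy threshold for commonness (strict).
#' @param replicate_mode \code{"pooled"} or \code{"per_rep"} attribution.
#' @param rarefaction a [rarefaction_policy()] for the clustering branch.
#' @param linkage clustering linkage.
#' @param rng_seed recorded seed for the run.
#' @param ... unknown keys -- always an error.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(counts, metadata, taxonomy, marker,
                       out_dir = tempfile("seedprov_run_"),
                       min_reads = 2,
                       blocklist = DEFAULT_BLOCKLIST,
                       identity_floor = 0.15,
                       presence_threshold = 0,
                       common_threshold = 0.6,
                       replicate_mode = c("pooled", "per_rep"),
                       rarefaction = rarefaction_policy(),
                       linkage = "upgma",
                       rng_seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config keys: ", paste(names(extra), collapse = ", "))
  }
  if (!marker %in% MARKERS) stop("marker must be one of ", paste(MARKERS, collapse = ", "))
  replicate_mode <- match.arg(replicate_mode)
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 marker = marker, out_dir = out_dir, min_reads = min_reads,
                 blocklist = blocklist, identity_floor = identity_floor,
                 presence_threshold = presence_threshold,
                 common_threshold = common_threshold,
                 replicate_mode = replicate_mode,
                 rarefaction = rarefaction, linkage = linkage,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as), x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full filtering / diversity / occupancy / provenance pipeline
#'
#' Executes, for one marker: OTU-level filters (minimum reads, non-target
#' blocklist); the pooled inventory branch (pool replicates, normalise,
#' per-compartment occupancy, common/core sets, seed and soil provenance
#' attribution, core seed-transmitted union, common-OTU provenance
#' classification); and the rarefied clustering branch (rarefy under the
#' policy, normalise, average replicates, Bray-Curtis, UPGMA ordering,
#' abundance-bin matrices). Every product is written as TSV/Newick/JSON under
#' \code{config$out_dir}, together with a JSON run log carrying the package
#' version, the verbatim configuration, per-stage record counts and md5
#' checksums of the outputs. Deterministic for a fixed configuration and
#' seed; any stage error aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the main in-memory products and the paths of
#'   everything written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- stage("read_counts", {
    if (is.character(config$counts)) read_otu_table(config$counts) else otu_table(config$counts)
  })
  tax <- stage("read_taxonomy", {
    if (is.character(config$taxonomy)) read_taxonomy(config$taxonomy) else
      validate_taxonomy(config$taxonomy)
  })
  meta <- stage("read_metadata", {
    m <- if (is.character(config$metadata)) read_sample_metadata(config$metadata) else
      validate_metadata(config$metadata)
    m <- m[m$marker == config$marker & m$sample_id %in% rownames(counts), , drop = FALSE]
    if (!nrow(m)) stop("no samples for marker ", config$marker)
    m
  })
  counts <- counts[intersect(rownames(counts), meta$sample_id), , drop = FALSE]
  validate_metadata(meta, counts)

  f1 <- stage("filter_min_reads", filter_min_reads(counts, config$min_reads))
  f2 <- stage("filter_nontarget",
              filter_nontarget(f1$counts, tax, config$blocklist, config$identity_floor))
  filtered <- f2$counts
  report <- rbind(f1$report, f2$report)

  # inventory branch: pool -> normalise -> occupancy/provenance
  pooled <- stage("pool_replicates", pool_replicates(filtered, meta))
  pooled_props <- to_proportions(pooled$counts)
  pmeta <- pooled$metadata

  div <- stage("diversity", {
    props <- to_proportions(filtered)
    data.frame(sample_id = rownames(filtered),
               reads = rowSums(filtered),
               richness = apply(filtered, 1L, richness),
               shannon_h = apply(props, 1L, shannon_h),
               stringsAsFactors = FALSE, row.names = NULL)
  })

  occ <- stage("occupancy", {
    strata <- unique(pmeta[pmeta$compartment %in% VEG_COMPARTMENTS,
                           c("compartment", "substrate")])
    seed_strata <- unique(pmeta[pmeta$compartment %in% SEED_COMPARTMENTS,
                                c("compartment", "substrate")])
    strata <- rbind(seed_strata, strata)
    res <- lapply(seq_len(nrow(strata)), function(i) {
      sel <- pmeta$compartment == strata$compartment[i] &
        pmeta$substrate == strata$substrate[i]
      occupancy(pooled_props, pmeta$sample_id[sel], config$presence_threshold)
    })
    names(res) <- paste(strata$compartment, strata$substrate, sep = ".")
    res
  })
  occ_report <- occupancy_abundance_report(occ, config$common_threshold)

  prov <- stage("provenance",
                provenance_matrix(filtered, meta, config$presence_threshold,
                                  config$replicate_mode))
  prov_avg <- summarize_provenance(prov)

  core_union <- stage("core_union",
                      core_seed_transmitted_union(pooled_props, pmeta,
                                                  config$presence_threshold))

  classif <- stage("classify_common", {
    res <- lapply(VEG_COMPARTMENTS, function(cpt) {
      soil_sel <- pmeta$compartment == cpt & pmeta$substrate == "soil"
      sand_sel <- pmeta$compartment == cpt & pmeta$substrate == "sand"
      if (!any(soil_sel) || !any(sand_sel)) return(NULL)
      soil_occ <- occupancy(pooled_props, pmeta$sample_id[soil_sel],
                            config$presence_threshold)
      sand_occ <- occupancy(pooled_props, pmeta$sample_id[sand_sel],
                            config$presence_threshold)
      cbind(compartment = cpt,
            classify_common_provenance(soil_occ, sand_occ, config$common_threshold),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })

  # clustering branch: rarefy -> normalise -> average -> Bray-Curtis/UPGMA
  clust <- stage("clustering", {
    rare <- rarefy_table(filtered, meta, config$rarefaction)
    props <- to_proportions(rare)
    avg <- average_proportions(props, meta)
    out <- list()
    for (cpt in VEG_COMPARTMENTS) {
      sel <- avg$metadata$compartment == cpt
      if (sum(sel) < 2L) next
      sub <- avg$props[avg$metadata$sample_id[sel], , drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      if (nrow(sub) < 2L) next
      d <- bray_curtis_matrix(sub)
      tree <- cluster_samples(d, config$linkage)
      out[[cpt]] <- list(dist = d, tree = tree,
                         bins = bin_matrix(sub[leaf_order(tree), , drop = FALSE]))
    }
    out
  })

  paths <- stage("write_outputs", {
    p <- character(0)
    p["filtered_counts"] <- write_otu_table(filtered, file.path(config$out_dir, "filtered_counts.tsv"))
    p["filter_report"] <- write_tsv(report, file.path(config$out_dir, "filter_report.tsv"))
    p["diversity"] <- write_tsv(div, file.path(config$out_dir, "diversity_summary.tsv"))
    p["occupancy_report"] <- write_tsv(occ_report, file.path(config$out_dir, "occupancy_report.tsv"))
    p["provenance"] <- write_tsv(prov, file.path(config$out_dir, "provenance_summary.tsv"))
    p["provenance_averages"] <- write_tsv(prov_avg, file.path(config$out_dir, "provenance_averages.tsv"))
    p["core_union"] <- write_tsv(data.frame(otu_id = as.character(core_union)),
                                 file.path(config$out_dir, "core_seed_transmitted.tsv"))
    if (!is.null(classif)) {
      p["classification"] <- write_tsv(classif, file.path(config$out_dir, "common_provenance.tsv"))
    }
    for (cpt in names(clust)) {
      p[paste0("tree_", cpt)] <- file.path(config$out_dir, paste0("tree_", cpt, ".nwk"))
      as_newick(clust[[cpt]]$tree, p[paste0("tree_", cpt)])
      p[paste0("distance_", cpt)] <- write_tsv(clust[[cpt]]$dist,
        file.path(config$out_dir, paste0("braycurtis_", cpt, ".tsv")), "sample_id")
      p[paste0("bins_", cpt)] <- write_tsv(clust[[cpt]]$bins,
        file.path(config$out_dir, paste0("bins_", cpt, ".tsv")), "sample_id")
    }
    jsonlite::write_json(list(bins = abundance_bins()),
                         file.path(config$out_dir, "bin_legend.json"))
    p["bin_legend"] <- file.path(config$out_dir, "bin_legend.json")
    p
  })

  log <- stage("run_log", {
    cfg_echo <- config
    for (big in c("counts", "metadata", "taxonomy")) {
      if (!is.character(cfg_echo[[big]])) cfg_echo[[big]] <- "<in-memory>"
    }
    cfg_echo$rarefaction <- unclass(cfg_echo$rarefaction)
    log <- list(
      package = "seedprov",
      version = as.character(utils::packageVersion("seedprov")),
      marker = config$marker,
      config = unclass(cfg_echo),
      records = list(
        samples_in = nrow(counts), otus_in = ncol(counts),
        otus_removed_min_reads = sum(f1$report$removed),
        otus_removed_non_target = sum(f2$report$removed),
        otus_flagged_low_identity = sum(!f2$report$removed),
        reads_removed = attr(f1$report, "reads_removed") +
          attr(f2$report, "reads_removed"),
        otus_analysed = ncol(filtered),
        core_seed_transmitted = length(core_union)
      ),
      output_md5 = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log
  })

  invisible(list(filtered = filtered, report = report, diversity = div,
                 pooled = pooled, occupancy = occ, occupancy_report = occ_report,
                 provenance = prov, provenance_averages = prov_avg,
                 core_seed_transmitted = core_union, classification = classif,
                 clustering = clust, paths = paths, log = log))
}
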