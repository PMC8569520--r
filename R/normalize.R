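#' Per-compartment rarefaction policy
#'
#' Records the target subsampling depth for each (marker, compartment)
#' stratum, whether undersampled samples are kept unrarefied, and the RNG
#' seed of the (single-draw) rarefaction. The defaults are the depths used
#' for the Bray-Curtis/clustering branch of the analysis: 16S -- 3,500 reads
#' per shoot, 3,000 per root, 6,500 per rhizosphere; ITS -- 1,000 per shoot,
#' 1,000 per root, 2,000 per rhizosphere. Seed and spermosphere samples carry
#' no depth and are never rarefied (they are analysed on the pooled,
#' proportion-normalised branch only).
#'
#' @param depths data.frame with columns marker, compartment, depth; NULL for
#'   the defaults above.
#' @param keep_undersampled keep samples whose total is at or below the target
#'   depth unchanged (rather than dropping them).
#' @param rng_seed integer seed recorded with, and used by, every rarefaction
#'   run under this policy.
#' @return list of class \code{"rarefaction_policy"}.
#' @export
rarefaction_policy <- function(depths = NULL, keep_undersampled = TRUE,
                               rng_seed = 1L) {
  if (is.null(depths)) {
    depths <- data.frame(
      marker = rep(c("16S", "ITS"), each = 3L),
      compartment = rep(c("shoot", "root", "rhizosphere"), 2L),
      depth = c(3500L, 3000L, 6500L, 1000L, 1000L, 2000L),
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("marker", "compartment", "depth") %in% names(depths))) {
    stop("depths needs columns marker, compartment, depth")
  }
  if (any(depths$depth <= 0)) stop("all rarefaction depths must be > 0")
  structure(list(depths = depths, keep_undersampled = isTRUE(keep_undersampled),
                 rng_seed = as.integer(rng_seed)),
            class = "rarefaction_policy")
}

#' Rarefy a count vector to a fixed depth
#'
#' Uniform subsampling of reads without replacement (multivariate
#' hypergeometric), a single draw per sample. Samples whose total is at or
#' below the target depth are returned unchanged -- low-count samples are
#' included without rarefaction rather than discarded. The output never
#' exceeds the input elementwise, so rarefaction can only shrink an OTU's
#' support.
#'
#' @param counts non-negative integer vector.
#' @param depth target total (>= 1).
#' @param seed optional integer; when given, the draw is made under this seed
#'   with the caller's RNG state restored afterwards.
#' @return integer vector of the same length and names.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("depth must be a single integer >= 1")
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  total <- sum(counts)
  if (total <= depth) return(counts)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  reads <- rep.int(seq_along(counts), counts)
  kept <- reads[sample.int(total, depth)]
  out <- tabulate(kept, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Rarefy an OTU table under a rarefaction policy
#'
#' Applies [rarefy()] sample by sample, looking up each sample's depth from
#' its (marker, compartment) stratum. Samples in strata without a configured
#' depth (seed, spermosphere by default) pass through unchanged. Samples are
#' processed in sorted sample-id order under \code{policy$rng_seed}, so the
#' result is bit-reproducible and independent of input row order.
#'
#' @param counts samples x OTUs integer matrix.
#' @param meta sample metadata covering the table.
#' @param policy a [rarefaction_policy()].
#' @return rarefied integer matrix in the input's row order.
#' @export
rarefy_table <- function(counts, meta, policy = rarefaction_policy()) {
  counts <- otu_table(counts)
  meta <- validate_metadata(meta, counts)
  if (!inherits(policy, "rarefaction_policy")) stop("policy must be a rarefaction_policy")
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  key <- paste(meta$marker, meta$compartment)
  pol_key <- paste(policy$depths$marker, policy$depths$compartment)
  depth <- policy$depths$depth[match(key, pol_key)]
  out <- counts
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(policy$rng_seed)
  for (sid in sort(rownames(counts))) {
    d <- depth[match(sid, rownames(counts))]
    if (is.na(d)) next
    out[sid, ] <- rarefy(counts[sid, ], d)
  }
  out
}

#' Transform counts to per-sample proportional abundance
#'
#' Each sample (row) is divided by its total read count. Zero-total samples
#' are kept as all-zero rows and flagged in the \code{"empty_samples"}
#' attribute rather than turned into NaN.
#'
#' @param counts samples x OTUs matrix (counts, or any non-negative values).
#' @return numeric matrix of row proportions with attribute
#'   \code{"empty_samples"} (character vector of zero-total sample ids).
#' @export
to_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts)
  props <- counts / ifelse(totals > 0, totals, 1)
  attr(props, "empty_samples") <- rownames(counts)[totals == 0]
  props
}

group_key <- function(meta, by) {
  do.call(paste, c(unname(meta[by]), sep = "."))
}

#' Pool replicate samples by summing reads
#'
#' The inventory-branch replicate scheme: reads from different replicates of
#' one (species, compartment, substrate, marker) stratum are summed into a
#' single pooled pseudo-sample, to be proportion-normalised afterwards.
#' Strata with no samples are simply absent, never zero-filled.
#'
#' @param counts samples x OTUs integer matrix.
#' @param meta sample metadata covering the table.
#' @param by grouping columns.
#' @return list with \code{counts} (pooled table; one row per stratum, sample
#'   id = dot-joined group key) and \code{metadata} (one row per stratum,
#'   \code{replicate} = number of pooled samples).
#' @export
pool_replicates <- function(counts, meta,
                            by = c("species", "compartment", "substrate", "marker")) {
  counts <- otu_table(counts)
  meta <- validate_metadata(meta, counts)
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  key <- group_key(meta, by)
  pooled <- rowsum(counts, group = key, reorder = TRUE)
  storage.mode(pooled) <- "integer"
  first <- meta[!duplicated(key), , drop = FALSE]
  first <- first[order(key[!duplicated(key)]), , drop = FALSE]
  pmeta <- data.frame(sample_id = rownames(pooled),
                      first[, setdiff(by, "sample_id"), drop = FALSE],
                      replicate = as.integer(table(key)[rownames(pooled)]),
                      stringsAsFactors = FALSE, row.names = NULL)
  # pooled pseudo-samples are not per-rep samples; replicate records the count
  list(counts = pooled, metadata = pmeta)
}

#' Average replicate proportion vectors
#'
#' The clustering-branch replicate scheme: per stratum, the arithmetic mean
#' of the (already rarefied and proportion-normalised) replicate rows. Empty
#' replicates are excluded from the mean, so the result stays on the simplex
#' whenever at least one replicate is non-empty; strata whose replicates are
#' all empty come out as zero rows flagged in \code{"empty_samples"}.
#'
#' @param props samples x OTUs proportion matrix (see [to_proportions()]).
#' @param meta sample metadata covering the rows.
#' @param by grouping columns.
#' @return list with \code{props} (one row per stratum) and \code{metadata}.
#' @export
average_proportions <- function(props, meta,
                                by = c("species", "compartment", "substrate", "marker")) {
  props <- as.matrix(props)
  meta <- validate_metadata(meta)
  if (!all(rownames(props) %in% meta$sample_id)) {
    stop("samples without metadata: ",
         paste(setdiff(rownames(props), meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(rownames(props), meta$sample_id), ]
  key <- group_key(meta, by)
  nonempty <- rowSums(props) > 0
  keys <- sort(unique(key))
  out <- matrix(0, nrow = length(keys), ncol = ncol(props),
                dimnames = list(keys, colnames(props)))
  for (k in keys) {
    sel <- key == k & nonempty
    if (any(sel)) out[k, ] <- colMeans(props[sel, , drop = FALSE])
  }
  first <- meta[!duplicated(key), , drop = FALSE]
  first <- first[order(key[!duplicated(key)]), , drop = FALSE]
  ameta <- data.frame(sample_id = keys,
                      first[, setdiff(by, "sample_id"), drop = FALSE],
                      replicate = as.integer(table(key)[keys]),
                      stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "empty_samples") <- keys[rowSums(out) == 0]
  list(props = out, metadata = ameta)
}
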