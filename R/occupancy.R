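#' Per-OTU occupancy and mean abundance within a sample group
#'
#' Occupancy is the exact rational fraction of the selected samples in which
#' an OTU is present (proportion strictly above \code{presence_threshold});
#' mean abundance is the arithmetic mean of its proportions over all group
#' members, zeros included. Presence-based, so occupancy is invariant to any
#' monotone rescaling of the non-zero proportions.
#'
#' @param props samples x OTUs proportion matrix.
#' @param samples optional row selector (character ids, logical or integer
#'   indices); default: all rows.
#' @param presence_threshold proportion above which an OTU counts as present.
#' @return data.frame with columns otu_id, n_present, n_total, occupancy,
#'   mean_abundance.
#' @export
occupancy <- function(props, samples = NULL, presence_threshold = 0) {
  props <- as.matrix(props)
  if (!is.null(samples)) props <- props[samples, , drop = FALSE]
  if (nrow(props) == 0) stop("empty sample group")
  present <- props > presence_threshold
  data.frame(
    otu_id = colnames(props),
    n_present = as.integer(colSums(present)),
    n_total = nrow(props),
    occupancy = colSums(present) / nrow(props),
    mean_abundance = colMeans(props),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Common OTUs: occupancy strictly above a threshold
#'
#' "More than 60%" is a strict inequality: in a 17-species panel an OTU must
#' be present in at least 11 species (11/17 = 0.647), while 10/17 = 0.588
#' does not qualify.
#'
#' @param occ an [occupancy()] result.
#' @param threshold occupancy threshold in \[0, 1).
#' @return character vector of OTU ids.
#' @export
common_otus <- function(occ, threshold = 0.6) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  occ$otu_id[occ$occupancy > threshold]
}

#' Core OTUs: occupancy exactly 100%
#'
#' @param occ an [occupancy()] result.
#' @return character vector of OTU ids present in every sample of the group.
#' @export
core_otus <- function(occ) {
  occ$otu_id[occ$n_present == occ$n_total]
}

#' Abundance bin labels
#'
#' The ordered heatmap colour categories: exactly zero, then left-open
#' right-closed intervals (0, 0.1\%], (0.1, 0.25\%], (0.25, 0.5\%],
#' (0.5, 1\%], (1, 5\%], (5, 100\%].
#'
#' @return character vector of ordered bin labels.
#' @export
abundance_bins <- function() {
  c("zero", "<=0.1%", "0.1-0.25%", "0.25-0.5%", "0.5-1%", "1-5%", ">5%")
}

#' Bin read percentages into heatmap abundance categories
#'
#' @param p numeric vector of percentages in \[0, 100\].
#' @return ordered factor over [abundance_bins()].
#' @export
bin_abundance <- function(p) {
  if (any(p < 0 | p > 100, na.rm = TRUE)) stop("percentages must lie in [0, 100]")
  labs <- abundance_bins()
  out <- as.character(cut(p, breaks = c(0, 0.1, 0.25, 0.5, 1, 5, 100),
                          labels = labs[-1L], right = TRUE))
  out[p == 0] <- "zero"
  factor(out, levels = labs, ordered = TRUE)
}

#' Bin a proportion matrix into abundance-category codes
#'
#' @param props proportion matrix (fractions in \[0, 1\]).
#' @return character matrix of bin labels, same dimnames.
#' @export
bin_matrix <- function(props) {
  props <- as.matrix(props)
  out <- matrix(as.character(bin_abundance(as.numeric(props) * 100)),
                nrow = nrow(props), dimnames = dimnames(props))
  out
}

#' Ranked occupancy-abundance report
#'
#' OTUs ranked by occupancy (descending), ties broken by mean abundance
#' (descending), then by otu_id -- so the report is a deterministic function
#' of its input regardless of row order. Columns flag membership in the
#' common set and mean read percentage above the high-abundance mark.
#'
#' @param occ an [occupancy()] result, or a named list of them (one per
#'   compartment), ranked within each element.
#' @param common_threshold occupancy threshold for the common flag.
#' @param abundant_pct mean-abundance percentage above which the
#'   high-abundance flag is set.
#' @return data.frame with columns group (when a list is given), rank,
#'   otu_id, n_present, n_total, occupancy, mean_abundance_pct, common,
#'   high_abundance.
#' @export
occupancy_abundance_report <- function(occ, common_threshold = 0.6,
                                       abundant_pct = 5) {
  rank_one <- function(o, group = NULL) {
    ord <- order(-o$occupancy, -o$mean_abundance, o$otu_id)
    o <- o[ord, , drop = FALSE]
    out <- data.frame(
      rank = seq_len(nrow(o)),
      otu_id = o$otu_id, n_present = o$n_present, n_total = o$n_total,
      occupancy = o$occupancy,
      mean_abundance_pct = o$mean_abundance * 100,
      common = o$occupancy > common_threshold,
      high_abundance = o$mean_abundance * 100 > abundant_pct,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (!is.null(group)) out <- cbind(group = group, out, stringsAsFactors = FALSE)
    out
  }
  if (is.data.frame(occ)) return(rank_one(occ))
  if (is.null(names(occ))) stop("a list of occupancy results must be named")
  do.call(rbind, lapply(names(occ), function(g) rank_one(occ[[g]], g)))
}

#' Joint occupancy view across compartments
#'
#' One row per OTU with each compartment's occupancy side by side, ranked by
#' mean occupancy across compartments (ties by otu_id).
#'
#' @param occ_list named list of [occupancy()] results over the same OTUs.
#' @return data.frame with one occupancy column per list element.
#' @export
joint_occupancy_view <- function(occ_list) {
  if (is.null(names(occ_list))) stop("occ_list must be named")
  ids <- sort(unique(unlist(lapply(occ_list, `[[`, "otu_id"))))
  cols <- lapply(occ_list, function(o) o$occupancy[match(ids, o$otu_id)])
  out <- data.frame(otu_id = ids, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$mean_occupancy <- rowMeans(as.matrix(out[, -1L, drop = FALSE]), na.rm = TRUE)
  out[order(-out$mean_occupancy, out$otu_id), , drop = FALSE]
}
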