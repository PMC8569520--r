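#' Filter reports
#'
#' Both OTU-level filters return, next to the filtered table, a report
#' data.frame with one row per affected OTU: \code{otu_id}, \code{reason}
#' (one of \code{below_min_reads}, \code{non_target},
#' \code{flagged_low_identity}), \code{removed} (logical; flagged OTUs are
#' listed but retained) and \code{reads} (total reads of that OTU in the
#' input). The attribute \code{"reads_removed"} carries the exact number of
#' reads taken out, so that reads removed + reads retained always equals the
#' input total.
#'
#' @name filter-report
#' @keywords internal
NULL

new_filter_report <- function(otu_id, reason, removed, reads, reads_removed) {
  rep <- data.frame(otu_id = as.character(otu_id), reason = as.character(reason),
                    removed = as.logical(removed), reads = as.numeric(reads),
                    stringsAsFactors = FALSE)
  attr(rep, "reads_removed") <- reads_removed
  rep
}

#' Remove OTUs below a minimum total read count
#'
#' Drops every OTU whose total raw read count, summed over all samples of the
#' table, is below \code{min_total}. The default of 2 keeps only OTUs
#' supported by at least two raw reads; an OTU with exactly \code{min_total}
#' reads is retained. Applied per marker table (16S and ITS are processed
#' independently).
#'
#' @param counts samples x OTUs integer matrix.
#' @param min_total minimum total reads for retention (>= 1).
#' @return list with elements \code{counts} (filtered table) and
#'   \code{report} (see filter-report).
#' @export
filter_min_reads <- function(counts, min_total = 2) {
  counts <- otu_table(counts)
  if (!is.numeric(min_total) || length(min_total) != 1L || min_total < 1) {
    stop("min_total must be a single number >= 1")
  }
  totals <- colSums(counts)
  drop <- totals < min_total
  report <- new_filter_report(colnames(counts)[drop],
                              rep("below_min_reads", sum(drop)),
                              rep(TRUE, sum(drop)),
                              totals[drop],
                              reads_removed = sum(totals[drop]))
  list(counts = counts[, !drop, drop = FALSE], report = report)
}

#' Remove non-target OTUs by taxonomy blocklist
#'
#' OTUs whose lineage or annotations contain any blocklist keyword
#' (case-insensitive substring over the concatenated lineage + annotations)
#' are removed with reason \code{non_target} -- chloroplast, mitochondrial,
#' plant-ribosomal and protist sequences in the default blocklist. OTUs whose
#' classifier confidence/identity falls below \code{identity_floor} but match
#' no keyword are retained and listed with reason
#' \code{flagged_low_identity}: the manual curation step becomes an explicit
#' review artifact rather than a silent judgment call.
#'
#' @param counts samples x OTUs integer matrix.
#' @param tax taxonomy data.frame (see [read_taxonomy()]); must cover every
#'   OTU in the table.
#' @param blocklist non-empty character vector of lineage keywords.
#' @param identity_floor confidence below which unmatched OTUs are flagged.
#' @return list with \code{counts} and \code{report}.
#' @export
filter_nontarget <- function(counts, tax,
                             blocklist = DEFAULT_BLOCKLIST,
                             identity_floor = 0.15) {
  counts <- otu_table(counts)
  tax <- validate_taxonomy(tax)
  if (!length(blocklist)) stop("blocklist must be non-empty")
  missing_ids <- setdiff(colnames(counts), tax$otu_id)
  if (length(missing_ids)) {
    stop("OTUs absent from taxonomy: ", paste(missing_ids, collapse = ", "))
  }
  tax <- tax[match(colnames(counts), tax$otu_id), ]
  haystack <- tolower(paste(tax$lineage, tax$annotations))
  hit <- Reduce(`|`, lapply(tolower(blocklist), function(k) {
    grepl(k, haystack, fixed = TRUE)
  }))
  low <- !hit & tax$confidence < identity_floor
  totals <- colSums(counts)
  report <- new_filter_report(
    c(colnames(counts)[hit], colnames(counts)[low]),
    c(rep("non_target", sum(hit)), rep("flagged_low_identity", sum(low))),
    c(rep(TRUE, sum(hit)), rep(FALSE, sum(low))),
    c(totals[hit], totals[low]),
    reads_removed = sum(totals[hit])
  )
  list(counts = counts[, !hit, drop = FALSE], report = report)
}
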