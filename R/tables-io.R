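#' Construct and validate an OTU count table
#'
#' The universal currency of the pipeline: a non-negative integer matrix with
#' samples as rows and OTUs as columns, both uniquely named. On-disk OTU
#' tables (TSV, BIOM) store OTUs as rows and samples as columns; readers and
#' writers transpose.
#'
#' @param counts matrix (or object coercible to one) of non-negative integer
#'   read counts; rows are samples, columns OTUs, both with unique names.
#' @return validated integer matrix with class-checked dimnames.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("otu_table requires sample (row) and OTU (column) names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table from TSV or BIOM
#'
#' TSV dialect: OTUs as rows, samples as columns, first column the OTU id,
#' tab separated, UTF-8. BIOM files are read through \pkg{biomformat}
#' (JSON BIOM). Either route returns the same in-memory orientation
#' (samples x OTUs).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return integer matrix, samples x OTUs (see [otu_table()]).
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(t(m)))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("OTU table must have an otu_id column plus >=1 sample column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated otu_id rows in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
  if (anyNA(m) || length(bad)) {
    idx <- which(is.na(m) | is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))))
    rc <- arrayInd(idx[1L], dim(m))
    stop("malformed numeric cell in ", path, " at OTU '", ids[rc[1L]],
         "', sample '", colnames(m)[rc[2L]], "'")
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  otu_table(t(m))
}

#' Write an OTU count table to TSV or BIOM
#'
#' @param counts samples x OTUs integer matrix.
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_otu_table <- function(counts, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  counts <- otu_table(counts)
  if (format == "biom") {
    b <- biomformat::make_biom(t(counts))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  out <- data.frame(otu_id = colnames(counts), t(counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a taxonomy table
#'
#' Taxonomy TSV columns: \code{otu_id}, \code{lineage} (rank-prefixed string,
#' e.g. \code{"d__Bacteria; p__Proteobacteria; g__Pantoea"}),
#' \code{confidence} (classifier confidence or identity, in \[0,1\]) and an
#' optional free-text \code{annotations} column. Missing ranks stay as absent
#' prefixes in the lineage string, never silently dropped from it.
#'
#' @param path file path.
#' @return data.frame with columns otu_id, lineage, confidence, annotations.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tax <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("otu_id", "lineage", "confidence") %in% names(tax))) {
    stop("taxonomy file needs columns otu_id, lineage, confidence")
  }
  if (!"annotations" %in% names(tax)) tax$annotations <- ""
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame.
#' @export
write_taxonomy <- function(tax, path) {
  tax <- validate_taxonomy(tax)
  utils::write.table(tax[, c("otu_id", "lineage", "confidence", "annotations")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$otu_id)) stop("duplicated otu_id in taxonomy")
  if (any(!nzchar(trimws(tax$lineage)))) {
    stop("every lineage needs at least one rank; use an explicit placeholder")
  }
  tax$confidence <- as.numeric(tax$confidence)
  if (anyNA(tax$confidence) || any(tax$confidence < 0 | tax$confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  if (is.null(tax$annotations)) tax$annotations <- ""
  tax$annotations[is.na(tax$annotations)] <- ""
  tax
}

#' Read, write and validate per-sample metadata
#'
#' Metadata TSV columns: \code{sample_id}, \code{species},
#' \code{compartment} (one of seed, spermosphere, rhizosphere, root, shoot),
#' \code{substrate} (none, sand, soil), \code{replicate} (positive integer)
#' and \code{marker} (16S or ITS). Metadata is an explicit sidecar table; a
#' convenience parser for conventional sample names exists
#' ([parse_sample_names()]) but is never applied implicitly.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8")
  validate_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate sample metadata, optionally against an OTU table
#'
#' Checks the controlled vocabularies, that seed and spermosphere samples
#' carry substrate \code{"none"}, and (when \code{counts} is given) that every
#' sample in the table has exactly one metadata record.
#'
#' @param meta metadata data.frame.
#' @param counts optional samples x OTUs matrix to cross-check coverage.
#' @return the validated metadata, invisibly usable in place.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  needed <- c("sample_id", "species", "compartment", "substrate", "replicate", "marker")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) stop("metadata missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  if (!all(meta$compartment %in% COMPARTMENTS)) {
    stop("unknown compartment: ",
         paste(setdiff(meta$compartment, COMPARTMENTS), collapse = ", "))
  }
  if (!all(meta$substrate %in% SUBSTRATES)) {
    stop("unknown substrate: ",
         paste(setdiff(meta$substrate, SUBSTRATES), collapse = ", "))
  }
  if (!all(meta$marker %in% MARKERS)) {
    stop("unknown marker: ", paste(setdiff(meta$marker, MARKERS), collapse = ", "))
  }
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$replicate) || any(meta$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  pre <- meta$compartment %in% SEED_COMPARTMENTS
  if (any(meta$substrate[pre] != "none")) {
    stop("seed and spermosphere samples must have substrate 'none': ",
         paste(meta$sample_id[pre & meta$substrate != "none"], collapse = ", "))
  }
  if (!is.null(counts)) {
    uncovered <- setdiff(rownames(counts), meta$sample_id)
    if (length(uncovered)) {
      stop("samples without metadata: ", paste(uncovered, collapse = ", "))
    }
  }
  meta
}

#' Parse conventional sample names into metadata fields
#'
#' Optional helper for names in the style \code{"maize soil shoot #2"} or
#' \code{"maize seed #1"} (species, optional substrate, compartment, replicate
#' after \code{#}). Seed and spermosphere names carry no substrate token and
#' get substrate \code{"none"}.
#'
#' @param x character vector of sample names.
#' @param marker marker to record for all parsed samples.
#' @return metadata data.frame (see [read_sample_metadata()]).
#' @export
parse_sample_names <- function(x, marker = "16S") {
  pat <- "^\\s*(\\S+)\\s+(?:(sand|soil)\\s+)?(seed|spermosphere|rhizosphere|root|shoot)\\s*#\\s*(\\d+)\\s*$"
  ok <- grepl(pat, x)
  if (!all(ok)) stop("unparseable sample names: ", paste(x[!ok], collapse = ", "))
  species <- sub(pat, "\\1", x)
  substrate <- sub(pat, "\\2", x)
  compartment <- sub(pat, "\\3", x)
  replicate <- as.integer(sub(pat, "\\4", x))
  substrate[!nzchar(substrate)] <- "none"
  bad <- compartment %in% SEED_COMPARTMENTS & substrate != "none"
  if (any(bad)) stop("seed/spermosphere names must not carry a substrate: ",
                     paste(x[bad], collapse = ", "))
  validate_metadata(data.frame(
    sample_id = x, species = species, compartment = compartment,
    substrate = substrate, replicate = replicate, marker = marker,
    stringsAsFactors = FALSE
  ))
}
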