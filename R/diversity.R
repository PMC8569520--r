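#' Shannon diversity index
#'
#' H = -sum p_i log p_i over the non-zero entries of a relative-abundance
#' vector (counts are normalised internally). Natural log by default -- the
#' convention of the PAST software family -- with the base configurable.
#' An empty (all-zero) vector is undefined and returns NA, never 0.
#'
#' @param x non-negative numeric vector of counts or proportions.
#' @param base logarithm base.
#' @return numeric H >= 0, or NA for an empty vector.
#' @export
shannon_h <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("abundances must be non-negative")
  total <- sum(x)
  if (total == 0) return(NA_real_)
  p <- x[x > 0] / total
  -sum(p * log(p, base = base))
}

#' Observed richness
#'
#' Number of entries strictly above the presence threshold (default: any
#' positive abundance).
#'
#' @param x numeric vector of counts or proportions.
#' @param threshold presence threshold.
#' @return integer count.
#' @export
richness <- function(x, threshold = 0) {
  sum(x > threshold, na.rm = TRUE)
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' BC = 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i), in \[0, 1\] for
#' non-negative inputs. Undefined (NA) when both profiles are empty.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return numeric dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(x) + sum(y)
  if (denom == 0) return(NA_real_)
  1 - 2 * sum(pmin(x, y)) / denom
}

#' All-pairs Bray-Curtis distance matrix
#'
#' @param props samples x OTUs abundance matrix; empty (all-zero) rows are
#'   dropped and recorded in the \code{"dropped"} attribute.
#' @return symmetric labelled matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(props) {
  props <- as.matrix(props)
  empty <- rowSums(props) == 0
  dropped <- rownames(props)[empty]
  props <- props[!empty, , drop = FALSE]
  n <- nrow(props)
  d <- matrix(0, n, n, dimnames = list(rownames(props), rownames(props)))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- bray_curtis(props[i, ], props[j, ])
      }
    }
  }
  attr(d, "dropped") <- dropped
  d
}

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' UPGMA (average linkage) by default; single and complete linkage are also
#' available. Exactly tied merge candidates are resolved by merging the pair
#' whose clusters carry the lexicographically smallest leaf labels, so the
#' tree -- and the exported leaf order used to arrange heatmap columns -- is a
#' deterministic function of the labelled distance matrix, invariant to input
#' row permutation.
#'
#' @param d labelled symmetric distance matrix (>= 2 samples).
#' @param linkage \code{"upgma"} (alias \code{"average"}), \code{"single"} or
#'   \code{"complete"}.
#' @return object of class \code{"linkage_tree"}: merge matrix and heights in
#'   \code{\link[stats]{hclust}} convention, \code{labels}, \code{order}
#'   (leaf order), \code{method}.
#' @export
cluster_samples <- function(d, linkage = c("upgma", "average", "single", "complete")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "upgma") "average" else linkage
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("clustering needs at least 2 samples")
  labels <- rownames(d)
  D <- d
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  clid <- -seq_len(n)           # hclust convention: negative = singleton
  minlab <- labels              # lexicographically smallest leaf per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- Inf; bi <- bj <- NA_integer_
    for (a in seq_len(length(idx) - 1L)) {
      for (b in seq(a + 1L, length(idx))) {
        i <- idx[a]; j <- idx[b]
        dij <- D[i, j]
        if (dij < best) {
          best <- dij; bi <- i; bj <- j
        } else if (dij == best) {
          cand <- sort(c(minlab[i], minlab[j]))
          cur <- sort(c(minlab[bi], minlab[bj]))
          if (cand[1L] < cur[1L] || (cand[1L] == cur[1L] && cand[2L] < cur[2L])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    # put the cluster with the smaller leading label first, for determinism
    if (minlab[bj] < minlab[bi]) { tmp <- bi; bi <- bj; bj <- tmp }
    merge[step, ] <- c(clid[bi], clid[bj])
    height[step] <- best
    for (k in idx) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <- switch(method,
        average  = (size[bi] * D[bi, k] + size[bj] * D[bj, k]) / (size[bi] + size[bj]),
        single   = min(D[bi, k], D[bj, k]),
        complete = max(D[bi, k], D[bj, k])
      )
    }
    active[bj] <- FALSE
    size[bi] <- size[bi] + size[bj]
    minlab[bi] <- min(minlab[bi], minlab[bj])
    clid[bi] <- step
  }
  ord <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = method),
            class = "linkage_tree")
}

tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  as.integer(expand(nrow(merge)))
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "bray-curtis"),
            class = "hclust")
}

#' Export a linkage tree as a Newick string
#'
#' @param tree a \code{linkage_tree} (or \code{hclust}).
#' @param path optional file to write to.
#' @return Newick string, invisibly when written to file.
#' @export
as_newick <- function(tree, path = NULL) {
  if (inherits(tree, "linkage_tree")) tree <- stats::as.hclust(tree)
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Leaf order of a clustering, as labels
#'
#' @param tree a \code{linkage_tree}.
#' @return character vector of labels in dendrogram order.
#' @export
leaf_order <- function(tree) {
  tree$labels[tree$order]
}

#' Extract a rank from a rank-prefixed lineage string
#'
#' Lineages use RDP-style rank prefixes (\code{d__}/\code{k__}, \code{p__},
#' \code{c__}, \code{o__}, \code{f__}, \code{g__}) joined by semicolons.
#' Absent or empty ranks return \code{"unknown"}.
#'
#' @param lineage character vector of lineage strings.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return character vector of rank values.
#' @export
lineage_rank <- function(lineage,
                         rank = c("phylum", "domain", "class", "order", "family", "genus")) {
  rank <- match.arg(rank)
  prefix <- c(domain = "[dk]", phylum = "p", class = "c",
              order = "o", family = "f", genus = "g")[[rank]]
  pat <- paste0("(?:^|;)\\s*", prefix, "__([^;]*)")
  m <- regmatches(lineage, regexpr(pat, lineage, perl = TRUE))
  out <- rep("unknown", length(lineage))
  hit <- grepl(pat, lineage, perl = TRUE)
  val <- trimws(sub(pat, "\\1", m, perl = TRUE))
  out[hit] <- ifelse(nzchar(val), val, "unknown")
  out
}

#' Phylum-level composition by sample group
#'
#' Collapses OTU proportions to phylum proportions per sample, then averages
#' over the non-empty samples of each group. OTUs without a phylum rank are
#' bucketed as \code{"unknown"}. Per group, phylum proportions sum to 1
#' whenever the group has any non-empty sample.
#'
#' @param props samples x OTUs proportion matrix.
#' @param tax taxonomy covering every OTU.
#' @param groups character/factor vector assigning each row of \code{props}
#'   to a group (recycled names must match rownames), or NULL for one group.
#' @return data.frame with columns group, phylum, proportion.
#' @export
phylum_composition <- function(props, tax, groups = NULL) {
  props <- as.matrix(props)
  tax <- validate_taxonomy(tax)
  missing_ids <- setdiff(colnames(props), tax$otu_id)
  if (length(missing_ids)) {
    stop("OTUs absent from taxonomy: ", paste(missing_ids, collapse = ", "))
  }
  phylum <- lineage_rank(tax$lineage[match(colnames(props), tax$otu_id)], "phylum")
  if (is.null(groups)) groups <- rep("all", nrow(props))
  if (!is.null(names(groups))) groups <- groups[rownames(props)]
  groups <- as.character(groups)
  by_phylum <- t(rowsum(t(props), group = phylum, reorder = TRUE))
  nonempty <- rowSums(props) > 0
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sel <- groups == g & nonempty
    m <- if (any(sel)) colMeans(by_phylum[sel, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(by_phylum)), colnames(by_phylum))
    data.frame(group = g, phylum = names(m), proportion = as.numeric(m),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}
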