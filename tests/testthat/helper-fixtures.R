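# small randomized fixtures shared across test files

random_counts <- function(n_samples = 5, n_otus = 8, lambda = 4,
                          prefix = "S", otu_prefix = "OTU") {
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0(prefix, seq_len(n_samples)),
                              paste0(otu_prefix, seq_len(n_otus))))
  storage.mode(m) <- "integer"
  m
}

random_simplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

random_distance_matrix <- function(n, labels = paste0("L", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# minimal 2-species design grid (both substrates, all compartments, 1 marker)
tiny_meta <- function(marker = "16S") {
  rows <- list()
  for (sp in c("alpha", "beta")) {
    for (cpt in c("seed", "spermosphere")) {
      for (r in 1:2) rows[[length(rows) + 1]] <-
          data.frame(sample_id = paste(sp, cpt, "none", r, marker, sep = "_"),
                     species = sp, compartment = cpt, substrate = "none",
                     replicate = r, marker = marker)
    }
    for (cpt in c("rhizosphere", "root", "shoot")) {
      for (sub in c("sand", "soil")) {
        for (r in 1:2) rows[[length(rows) + 1]] <-
            data.frame(sample_id = paste(sp, cpt, sub, r, marker, sep = "_"),
                       species = sp, compartment = cpt, substrate = sub,
                       replicate = r, marker = marker)
      }
    }
  }
  do.call(rbind, rows)
}

tiny_taxonomy <- function(otu_ids, phylum = "Proteobacteria") {
  data.frame(otu_id = otu_ids,
             lineage = paste0("d__Bacteria; p__", phylum, "; g__Genus"),
             confidence = 0.99, annotations = "",
             stringsAsFactors = FALSE)
}

# independent brute-force occupancy oracle: plain loops, no matrix algebra
brute_occupancy <- function(props, threshold = 0) {
  res <- data.frame(otu_id = colnames(props), n_present = NA_integer_,
                    occupancy = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(props))) {
    n <- 0L
    for (i in seq_len(nrow(props))) if (props[i, j] > threshold) n <- n + 1L
    res$n_present[j] <- n
    res$occupancy[j] <- n / nrow(props)
  }
  res
}
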