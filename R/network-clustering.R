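#' Hierarchical clustering of interaction profiles
#'
#' Agglomerative average-linkage clustering of a filtered spectral-count
#' matrix (specific preys only, bait self-counts removed) under the Pearson
#' correlation distance `d = 1 - r`, computed on `log2(x + 1)`-transformed
#' counts. Both preys (rows) and runs (columns) are clustered. Rows or
#' columns with zero variance have no defined correlation; their distance to
#' everything else is set to 1 with a warning.
#'
#' @param counts numeric matrix, preys in rows, runs in columns (raw scale;
#'   set `log2_transform = FALSE` if already transformed)
#' @param log2_transform apply `log2(x + 1)` first (default `TRUE`)
#' @return a `cluster_result` list: `prey_hclust`, `run_hclust` (stats
#'   [stats::hclust()] trees), `prey_order`, `run_order` (leaf orders), and
#'   the transformed `matrix`
#' @export
cluster_matrix <- function(counts, log2_transform = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("clustering needs at least 2 preys and 2 runs")
  }
  x <- if (log2_transform) log2(counts + 1) else counts
  tree <- function(m) {
    d <- pearson_distance(m)
    stats::hclust(stats::as.dist(d), method = "average")
  }
  prey_h <- tree(x)
  run_h <- tree(t(x))
  structure(list(prey_hclust = prey_h, run_hclust = run_h,
                 prey_order = rownames(x)[prey_h$order],
                 run_order = colnames(x)[run_h$order],
                 matrix = x),
            class = "cluster_result")
}

pearson_distance <- function(m) {
  v <- apply(m, 1L, stats::var)
  flat <- v == 0 | is.na(v)
  if (any(flat)) {
    warning(sum(flat), " zero-variance profile(s); their correlation distance is set to 1")
  }
  r <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  d
}

#' Write a dendrogram as a Newick tree
#' @param h an [stats::hclust()] tree (e.g. from [cluster_matrix()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Normalized spectral abundance factors
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`: each protein's spectral
#' count is divided by its length (spectra scale with protein size) and the
#' length-normalized values are rescaled to sum to 1 over the protein set.
#'
#' @param counts named numeric vector of spectral counts per prey
#' @param lengths protein lengths in amino acids, same order/names (>= 1)
#' @return named NSAF vector summing to 1
#' @export
nsaf <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths >= 1))
  if (sum(counts) == 0) stop("all-zero counts: NSAF undefined")
  saf <- counts / lengths
  saf / sum(saf)
}

#' Abundance-normalized enrichment index
#'
#' The raw index of a prey is its NSAF (relative abundance in the isolate)
#' divided by its estimated whole-cell abundance, so preys enriched by the
#' purification beyond their cellular levels stand out. Indices are rescaled
#' so the chosen reference prey is exactly 1.
#'
#' @param nsaf_values named NSAF vector (see [nsaf()])
#' @param pax_abundance named vector of cellular abundances (e.g. PAX-style
#'   ppm); preys missing here get an `NA` index and a `flagged` mark
#' @param reference_prey gene symbol of the prey anchored at index 1
#' @return data.frame with columns `prey`, `nsaf`, `pax_abundance`,
#'   `enrichment_index`, `flagged`
#' @export
enrichment_index <- function(nsaf_values, pax_abundance, reference_prey) {
  reference_prey <- toupper(reference_prey)
  preys <- toupper(names(nsaf_values))
  names(pax_abundance) <- toupper(names(pax_abundance))
  pax <- unname(pax_abundance[preys])
  ri <- match(reference_prey, preys)
  if (is.na(ri)) stop("reference prey ", reference_prey, " has no NSAF")
  if (is.na(pax[ri]) || pax[ri] <= 0) {
    stop("reference prey ", reference_prey, " needs a positive abundance")
  }
  raw <- as.numeric(nsaf_values) / pax
  idx <- raw / raw[ri]
  idx[ri] <- 1  # exact by construction
  data.frame(prey = preys, nsaf = as.numeric(nsaf_values),
             pax_abundance = as.numeric(pax), enrichment_index = idx,
             flagged = is.na(pax), stringsAsFactors = FALSE)
}

#' Export a bait-prey interaction network
#'
#' Builds node and edge tables from classified profiles. Each passing,
#' non-contaminant, non-nonspecific prey contributes one edge per bait;
#' edge weight is the `log2(mean spectral count + 1)` of the prey over the
#' bait's runs when a count matrix is supplied.
#'
#' @param profiles classified profiles from [classify_profiles()], possibly
#'   concatenated over baits
#' @param counts optional `count_matrix`/`normalized_counts` used for edge
#'   weights
#' @param annotations optional data.frame (`gene`, `process`) of
#'   biological-process labels for nodes
#' @param known optional [reference_set()] used to flag known edges
#' @return list with `nodes` and `edges` data.frames
#' @export
export_network <- function(profiles, counts = NULL, annotations = NULL, known = NULL) {
  keep <- !profiles$category %in% c("contaminant", "nonspecific")
  e <- profiles[keep, , drop = FALSE]
  weight <- rep(NA_real_, nrow(e))
  if (!is.null(counts)) {
    for (i in seq_len(nrow(e))) {
      runs <- runs_for_bait(counts, e$bait[i])
      if (e$prey[i] %in% rownames(counts$counts) && length(runs)) {
        weight[i] <- log2(mean(counts$counts[e$prey[i], runs]) + 1)
      }
    }
  }
  edges <- data.frame(bait = e$bait, prey = e$prey, weight = weight,
                      category = as.character(e$category),
                      stringsAsFactors = FALSE)
  edges$known <- if (is.null(known)) NA else
    paste(edges$bait, edges$prey) %in% paste(known$pairs$bait, known$pairs$prey)
  genes <- unique(c(edges$bait, edges$prey))
  nodes <- data.frame(gene = genes,
                      role = ifelse(genes %in% edges$bait, "bait", "prey"),
                      stringsAsFactors = FALSE)
  nodes$process <- if (is.null(annotations)) NA_character_ else
    annotations$process[match(nodes$gene, toupper(annotations$gene))]
  list(nodes = nodes, edges = edges)
}

#' Write a network as SIF plus node/edge TSV tables
#'
#' @param network list from [export_network()]
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`
#' @return the three paths, invisibly
#' @export
write_network <- function(network, prefix) {
  sif <- file.path(paste0(prefix, ".sif"))
  writeLines(paste(network$edges$bait, "interacts", network$edges$prey, sep = "\t"), sif)
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  utils::write.table(network$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, ep, np))
}
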