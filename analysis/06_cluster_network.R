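#!/usr/bin/env Rscript
# Stage 6 — downstream summaries: clustering, enrichment indices, network.
#
# Clusters log2(x+1) spectral-count profiles of passing preys (Pearson
# correlation distance, average linkage; replicate runs of one bait should
# emerge as adjacent leaves), computes NSAF and abundance-normalized
# enrichment indices per bait (reference prey anchored at 1), and exports
# the bait-prey network as SIF + node/edge tables.

library(apmstability)

out <- "results"
m <- read_count_matrix(file.path(out, "counts.tsv"), "long")
m <- zero_bait_self_counts(clean_preys(m))
scored <- read.delim(file.path(out, "saint_results.tsv"))
profiles <- read.delim(file.path(out, "profiles.tsv"))
pax <- read.delim(file.path(out, "pax.tsv"))
baits <- unique(scored$bait)

passing <- unique(scored$prey[scored$passes])
cl <- cluster_matrix(m$counts[rownames(m$counts) %in% passing, ])
write.table(data.frame(prey = rownames(cl$matrix), cl$matrix, check.names = FALSE),
            file.path(out, "cluster_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_dendrogram_newick(cl$prey_hclust, file.path(out, "prey_dendrogram.nwk"))
write_dendrogram_newick(cl$run_hclust, file.path(out, "run_dendrogram.nwk"))
cat("run dendrogram leaf order:", paste(cl$run_order, collapse = " "), "\n")

enr <- do.call(rbind, lapply(baits, function(b) {
  pr <- scored$prey[scored$bait == b & scored$passes]
  ns <- nsaf(rowMeans(m$counts[pr, runs_for_bait(m, b), drop = FALSE]),
             m$preys$length[match(pr, m$preys$gene)])
  ref_prey <- names(sort(ns, decreasing = TRUE))[1]  # most abundant as anchor
  er <- enrichment_index(ns, setNames(pax$abundance, pax$gene), ref_prey)
  top <- er[order(-er$enrichment_index), ][1:3, ]
  cat(sprintf("%s: anchor %s; top enrichment indices: %s\n", b, ref_prey,
              paste(sprintf("%s=%.2f", top$prey, top$enrichment_index), collapse = ", ")))
  cbind(bait = b, er)
}))
write.table(enr, file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

net <- export_network(profiles, counts = m)
write_network(net, file.path(out, "network"))
cat(sprintf("network: %d nodes, %d edges\n", nrow(net$nodes), nrow(net$edges)))
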