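#!/usr/bin/env Rscript

# Stage 2 — spot clustering and marker detection.
#
# Reads the simulated file set from results/data, applies spot/gene QC,
# log1p-CPM normalization, PCA on the highly variable genes, builds the
# shared-nearest-neighbour graph and clusters it with Louvain, then
# detects per-cluster marker genes by one-vs-rest rank-sum tests. Also
# repeats the intratissue replicate-consistency check: two random
# disjoint halves of one tissue domain should show near-identical
# pseudo-bulk transcriptomes (R^2 well above 0.98), while halves drawn
# from different domains should not.

suppressMessages(library(spotnet))

seed <- 1L
ddir <- "results/data"
out <- "results/cluster"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

matrix <- read_count_matrix(file.path(ddir, "counts"))
truth <- jsonlite::read_json(file.path(ddir, "truth.json"))
domain_of <- unlist(truth$domain_of)

qc <- qc_filter(matrix, min_counts_per_spot = 100, min_spots_per_gene = 3)
norm <- normalize_log_cpm(qc)
emb <- run_pca(norm, n_pcs = 30L, genes = highly_variable_genes(norm))
graph <- build_knn_graph(emb, k = 15L)
clusters <- louvain_cluster(graph, resolution = 1.0, seed = seed)
ari <- mclust::adjustedRandIndex(clusters$labels,
                                 domain_of[names(clusters$labels)])
cat(sprintf("Louvain found %d clusters; ARI vs planted domains = %.3f\n",
            clusters$n_clusters, ari))

markers <- find_markers(norm, clusters)
cat(sprintf("%d marker rows; top marker of cluster 0: %s (log2FC %.2f, q = %.2g)\n",
            nrow(markers), markers$gene[1], markers$log2_fold_change[1],
            markers$q[1]))

# replicate consistency within and between domains
d0 <- names(domain_of)[domain_of == 0 & names(domain_of) %in% qc$barcodes]
d1 <- names(domain_of)[domain_of == 1 & names(domain_of) %in% qc$barcodes]
set.seed(seed)
half <- sample(d0, length(d0) %/% 2)
within <- replicate_consistency(qc, half, setdiff(d0, half))
between <- replicate_consistency(qc, d0, d1)
cat(sprintf("replicate consistency: within-domain R^2 = %.4f, between-domain R^2 = %.4f\n",
            within, between))

write.table(data.frame(barcode = names(clusters$labels),
                       cluster = unname(clusters$labels)),
            file.path(out, "clusters.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(markers, file.path(out, "markers.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(seed = seed, n_clusters = clusters$n_clusters,
                          domain_ari = ari, r2_within = within,
                          r2_between = between),
                     file.path(out, "summary.json"), auto_unbox = TRUE,
                     digits = NA)
cat("outputs written to", out, "\n")
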