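#' Spot and gene quality-control filter
#'
#' Drops spots whose total UMI count falls below `min_counts_per_spot`,
#' then genes detected (count > 0) in fewer than `min_spots_per_gene` of
#' the surviving spots. Geometry and annotation must be subset by the
#' caller to the returned barcodes/genes.
#'
#' @param matrix a [count_matrix()].
#' @param min_counts_per_spot,min_spots_per_gene non-negative thresholds.
#' @return a filtered [count_matrix()].
#' @export
qc_filter <- function(matrix, min_counts_per_spot = 0,
                      min_spots_per_gene = 0) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (min_counts_per_spot < 0 || min_spots_per_gene < 0) {
    stopf("QC thresholds must be >= 0")
  }
  keep_s <- Matrix::rowSums(matrix$counts) >= min_counts_per_spot
  if (!any(keep_s)) stopf("empty matrix after QC")
  m <- matrix$counts[keep_s, , drop = FALSE]
  keep_g <- Matrix::colSums(m > 0) >= min_spots_per_gene
  if (!any(keep_g)) stopf("empty matrix after QC")
  count_matrix(m[, keep_g, drop = FALSE], matrix$barcodes[keep_s],
               matrix$gene_ids[keep_g])
}

#' Library-size normalization to log1p counts-per-scale-factor
#'
#' `values[s, g] = log(1 + counts[s, g] * scale_factor / total_s)`. Spots
#' with zero total counts become all-zero rows with a warning.
#'
#' @param matrix a [count_matrix()].
#' @param scale_factor target per-spot total (default 1e4).
#' @return list of class `NormalizedMatrix` with dense `values`
#'   (spots x genes), `scale_factor`, `barcodes`, `gene_ids`.
#' @export
normalize_log_cpm <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (scale_factor <= 0) stopf("scale_factor must be positive")
  totals <- Matrix::rowSums(matrix$counts)
  if (any(totals == 0)) {
    warnf("%d spot(s) with zero total counts normalized to all-zero rows",
          sum(totals == 0))
  }
  denom <- ifelse(totals == 0, 1, totals)
  vals <- log1p(as.matrix(matrix$counts) * (scale_factor / denom))
  dimnames(vals) <- list(matrix$barcodes, matrix$gene_ids)
  structure(list(values = vals, scale_factor = scale_factor,
                 barcodes = matrix$barcodes, gene_ids = matrix$gene_ids),
            class = "NormalizedMatrix")
}

#' Highly variable genes by dispersion
#'
#' Ranks genes by variance-to-mean ratio of the normalized values and
#' returns the top `n` gene ids; the paper-style pipeline feeds these to
#' PCA.
#'
#' @param norm a [normalize_log_cpm()] result.
#' @param n number of genes to keep.
#' @return character vector of gene ids.
#' @export
highly_variable_genes <- function(norm, n = 2000L) {
  v <- apply(norm$values, 2, stats::var)
  m <- colMeans(norm$values)
  disp <- ifelse(m > 0, v / m, 0)
  norm$gene_ids[order(disp, decreasing = TRUE)][seq_len(min(n, length(disp)))]
}

#' Principal component embedding of spots
#'
#' Centers (and by default unit-scales) genes, then projects spots onto
#' the leading principal components. Component signs are fixed so the
#' largest-magnitude gene loading of each component is positive, making
#' the embedding deterministic.
#'
#' @param norm a [normalize_log_cpm()] result.
#' @param n_pcs number of components (<= min(spots, genes)).
#' @param center,scale_genes passed to the gene-wise standardization;
#'   zero-variance genes are left unscaled.
#' @param genes optional subset of gene ids (e.g. highly variable genes).
#' @return spots x n_pcs matrix with attribute `"sdev"` (component
#'   standard deviations, non-increasing).
#' @export
run_pca <- function(norm, n_pcs = 30L, center = TRUE, scale_genes = TRUE,
                    genes = NULL) {
  vals <- norm$values
  if (!is.null(genes)) vals <- vals[, genes, drop = FALSE]
  if (n_pcs > min(dim(vals))) {
    stopf("n_pcs (%d) exceeds min(spots, genes) = %d", n_pcs, min(dim(vals)))
  }
  if (scale_genes) {
    sds <- apply(vals, 2, stats::sd)
    sds[sds == 0] <- 1
  } else {
    sds <- FALSE
  }
  pc <- stats::prcomp(vals, center = center, scale. = if (isFALSE(sds)) FALSE else sds,
                      rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  emb <- sweep(pc$x, 2, flip, `*`)
  rownames(emb) <- norm$barcodes
  attr(emb, "sdev") <- pc$sdev[seq_len(n_pcs)]
  emb
}

#' Shared-nearest-neighbour graph of spots
#'
#' Connects i and j when either is among the other's `k` nearest
#' neighbours in the embedding (Euclidean metric), weighting each edge by
#' the Jaccard overlap of the two spots' neighbour sets (self included,
#' as is conventional for SNN graphs); zero-weight edges are dropped.
#'
#' @param embedding spots x dims matrix.
#' @param k number of nearest neighbours (0 < k < spots).
#' @return an undirected weighted [igraph::graph] with one vertex per
#'   spot, named by the embedding's row names.
#' @export
build_knn_graph <- function(embedding, k = 15L) {
  n <- nrow(embedding)
  if (k <= 0) stopf("k must be positive")
  if (k >= n) stopf("k (%d) must be smaller than the number of spots (%d)",
                    k, n)
  G <- tcrossprod(embedding)             # squared Euclidean via BLAS
  sq <- diag(G)
  d <- outer(sq, sq, "+") - 2 * G
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  # sparse neighbour-set indicator (self included, as is conventional);
  # A %*% t(A) then counts shared neighbours for every pair at once
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  B <- A
  diag(B) <- 0                           # directed knn edges without self
  und <- (B + Matrix::t(B)) > 0          # i-j iff either lists the other
  idx <- Matrix::which(und & upper.tri(und), arr.ind = TRUE)
  sh <- shared[idx]
  w <- sh / (2 * (k + 1L) - sh)          # Jaccard of the two (k+1)-sets
  keep <- w > 0
  g <- igraph::graph_from_edgelist(idx[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w[keep])
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::set_vertex_attr(g, "name", value = rownames(embedding))
}

#' Louvain community clustering of the spot graph
#'
#' Greedy modularity optimization at the given resolution; labels are
#' re-indexed by decreasing cluster size so label 0 is always the largest
#' cluster. A fixed seed makes the result deterministic.
#'
#' @param graph SNN graph from [build_knn_graph()].
#' @param resolution modularity resolution (> 0).
#' @param seed integer seed.
#' @param embedding optional embedding to carry along in the result.
#' @return list of class `ClusterResult`: `labels` (named 0-based integer
#'   vector), `n_clusters`, `resolution`, `embedding`, `graph`.
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = 1L,
                            embedding = NULL) {
  if (igraph::vcount(graph) == 0L) stopf("empty graph")
  if (igraph::ecount(graph) == 0L) {
    warnf("graph has no edges: every spot becomes its own cluster")
    memb <- seq_len(igraph::vcount(graph))
  } else {
    memb <- with_seed(derive_seed(seed, 41L),
      igraph::membership(igraph::cluster_louvain(graph,
                                                 resolution = resolution)))
  }
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- stats::setNames(unname(relabel[as.character(memb)]),
                            igraph::vertex_attr(graph, "name"))
  structure(list(labels = labels, n_clusters = length(sizes),
                 resolution = resolution, embedding = embedding,
                 graph = graph),
            class = "ClusterResult")
}

#' Sweep the Louvain resolution toward a requested cluster count
#'
#' Bisects the resolution until the clustering yields `target_clusters`
#' (or the closest achievable count within `max_iter` steps). The number
#' of clusters is not promised on arbitrary data; this helper mirrors the
#' common practice of tuning resolution to a desired granularity.
#'
#' @param graph SNN graph.
#' @param target_clusters desired cluster count.
#' @param seed integer seed.
#' @param lower,upper resolution bracket.
#' @param max_iter bisection steps.
#' @return the `ClusterResult` whose count is closest to the target
#'   (ties: lower resolution).
#' @export
sweep_resolution <- function(graph, target_clusters, seed = 1L,
                             lower = 0.05, upper = 4, max_iter = 12L) {
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    res <- louvain_cluster(graph, resolution = mid, seed = seed)
    if (is.null(best) ||
        abs(res$n_clusters - target_clusters) <
          abs(best$n_clusters - target_clusters)) {
      best <- res
    }
    if (res$n_clusters == target_clusters) return(res)
    if (res$n_clusters > target_clusters) upper <- mid else lower <- mid
  }
  best
}

#' Cluster marker genes by one-vs-rest rank-sum test
#'
#' For every cluster, each gene is tested in-cluster versus all other
#' spots with a two-sided Wilcoxon rank-sum test ([rank_sum_test()]).
#' Genes pass when expressed in at least `min_frac_in` of the cluster's
#' spots and when the log2 fold change (of mean expm1 expression, with a
#' unit pseudocount) is at least `min_log2fc`. q-values are BH-adjusted
#' over the whole tested set.
#'
#' @param norm a [normalize_log_cpm()] result.
#' @param clusters a `ClusterResult`.
#' @param min_frac_in minimum detected fraction within the cluster.
#' @param min_log2fc minimum log2 fold change.
#' @return data.frame `cluster`, `gene`, `log2_fold_change`, `frac_in`,
#'   `frac_out`, `p`, `q`, sorted within cluster by `q` then decreasing
#'   fold change.
#' @export
find_markers <- function(norm, clusters, min_frac_in = 0.1,
                         min_log2fc = 0.25) {
  if (clusters$n_clusters < 2L) stopf("need at least 2 clusters")
  labels <- clusters$labels[norm$barcodes]
  rows <- list()
  tested_p <- numeric(0)
  for (cl in 0:(clusters$n_clusters - 1L)) {
    inside <- which(labels == cl)
    if (length(inside) < 2L) {
      warnf("cluster %d has fewer than 2 spots: skipped", cl)
      next
    }
    outside <- which(labels != cl)
    vin <- norm$values[inside, , drop = FALSE]
    vout <- norm$values[outside, , drop = FALSE]
    frac_in <- colMeans(vin > 0)
    frac_out <- colMeans(vout > 0)
    lfc <- log2(colMeans(expm1(vin)) + 1) - log2(colMeans(expm1(vout)) + 1)
    cand <- which(frac_in >= min_frac_in & lfc >= min_log2fc)
    for (gi in cand) {
      p <- rank_sum_test(vin[, gi], vout[, gi])$p
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, gene = norm$gene_ids[gi], log2_fold_change = lfc[gi],
        frac_in = frac_in[gi], frac_out = frac_out[gi], p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(0), gene = character(0),
                      log2_fold_change = numeric(0), frac_in = numeric(0),
                      frac_out = numeric(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$cluster, out$q, -out$log2_fold_change, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intratissue replicate consistency
#'
#' Squared Pearson correlation between the pseudo-bulk mean log1p-CPM
#' profiles of two disjoint spot sets — the whole-transcriptome
#' consistency check used to argue that spatially separated regions of
#' one tissue are interchangeable replicates.
#'
#' @param matrix a [count_matrix()].
#' @param region_a,region_b disjoint non-empty barcode sets.
#' @param scale_factor normalization scale factor.
#' @return squared Pearson correlation (R^2) across all genes.
#' @export
replicate_consistency <- function(matrix, region_a, region_b,
                                  scale_factor = 1e4) {
  if (!length(region_a) || !length(region_b)) stopf("regions must be non-empty")
  if (length(intersect(region_a, region_b))) stopf("regions overlap")
  if (!all(c(region_a, region_b) %in% matrix$barcodes)) {
    stopf("regions contain unknown barcodes")
  }
  norm <- normalize_log_cpm(matrix, scale_factor)
  prof_a <- colMeans(norm$values[region_a, , drop = FALSE])
  prof_b <- colMeans(norm$values[region_b, , drop = FALSE])
  stats::cor(prof_a, prof_b)^2
}
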