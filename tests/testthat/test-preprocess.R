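test_that("qc_filter applies spot and gene thresholds", {
  m <- cm(matrix(c(5, 2, 0, 1, 5, 0, 0, 0), 2, 4))
  expect_equal(as.matrix(qc_filter(m, 0, 0)$counts), as.matrix(m$counts))

  # one all-zero gene removed, others untouched
  f <- qc_filter(m, 0, 1)
  expect_equal(f$gene_ids, c("G01", "G02", "G03"))

  # spot totals are 10 and 3: threshold 5 keeps one spot
  f2 <- qc_filter(m, 5, 0)
  expect_equal(f2$barcodes, "S01")
  expect_error(qc_filter(m, 100, 0), "empty matrix after QC")
})

test_that("normalization hits the closed form and is scale invariant", {
  m <- cm(matrix(c(1, 1), 1, 2))
  n <- normalize_log_cpm(m, 1e4)
  expect_equal(unname(n$values[1, ]), rep(log(5001), 2))

  m2 <- cm(matrix(c(1, 0, 1, 0), 2, 2))
  expect_warning(n2 <- normalize_log_cpm(m2), "zero total")
  expect_equal(unname(n2$values[2, ]), c(0, 0))

  # doubling a spot's counts leaves its normalized row unchanged
  m3 <- cm(matrix(c(3, 6, 1, 2, 7, 14), 2, 3, byrow = FALSE))
  m4 <- cm(2 * as.matrix(m3$counts))
  expect_equal(normalize_log_cpm(m3)$values, normalize_log_cpm(m4)$values,
               ignore_attr = TRUE)
})

test_that("normalized rows recover the scale factor", {
  set.seed(2)
  m <- cm(matrix(rpois(50, 4), 5, 10))
  n <- normalize_log_cpm(m, 1e4)
  expect_equal(unname(rowSums(expm1(n$values))), rep(1e4, 5), tolerance = 1e-6)
})

test_that("PCA matches the hand eigendecomposition of collinear points", {
  vals <- matrix(c(0, 1, 2, 0, 1, 2), 3, 2)
  norm <- structure(list(values = vals, scale_factor = 1,
                         barcodes = paste0("S", 1:3),
                         gene_ids = paste0("G", 1:2)),
                    class = "NormalizedMatrix")
  emb <- run_pca(norm, n_pcs = 2L, scale_genes = FALSE)
  expect_equal(unname(emb[, 1]), c(-sqrt(2), 0, sqrt(2)))
  sdev <- attr(emb, "sdev")
  expect_equal(sdev[2], 0)                      # PC2 carries no variance
  expect_equal(sdev[1]^2 / sum(sdev^2), 1)      # PC1 explains everything
  expect_true(all(diff(sdev) <= 1e-12))         # non-increasing variances
  expect_error(run_pca(norm, n_pcs = 5L), "exceeds")
})

test_that("the SNN graph respects neighbourhood structure", {
  set.seed(4)
  cloud_a <- matrix(rnorm(40, 0), 20, 2)
  cloud_b <- matrix(rnorm(40, 50), 20, 2)
  emb <- rbind(cloud_a, cloud_b)
  rownames(emb) <- sprintf("S%02d", 1:40)
  g <- build_knn_graph(emb, k = 5L)
  el <- igraph::as_edgelist(g, names = FALSE)
  same_side <- (el[, 1] <= 20) == (el[, 2] <= 20)
  expect_true(all(same_side))                   # no cross-cloud edges
  expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))

  # k = n - 1 yields the complete graph
  emb2 <- matrix(rnorm(12), 6, 2); rownames(emb2) <- paste0("S", 1:6)
  gc <- build_knn_graph(emb2, k = 5L)
  expect_equal(igraph::ecount(gc), choose(6, 2))
  expect_error(build_knn_graph(emb2, k = 0L), "positive")
  expect_error(build_knn_graph(emb2, k = 6L), "smaller")
})

test_that("Louvain recovers disconnected cliques and is deterministic", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::set_edge_attr(g, "weight", value = 1)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("S", 1:10))
  res <- louvain_cluster(g, seed = 1L)
  expect_equal(res$n_clusters, 2L)
  expect_length(unique(res$labels[1:5]), 1L)
  expect_length(unique(res$labels[6:10]), 1L)
  expect_setequal(unique(res$labels), c(0L, 1L))

  res2 <- louvain_cluster(g, seed = 1L)
  expect_identical(res$labels, res2$labels)

  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "name", value = paste0("S", 1:3))
  expect_warning(r0 <- louvain_cluster(g0), "no edges")
  expect_equal(r0$n_clusters, 3L)
})

test_that("labels are a complete 0-based partition ordered by size", {
  set.seed(8)
  emb <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(20, 30), 10, 2))
  rownames(emb) <- sprintf("S%02d", 1:40)
  res <- louvain_cluster(build_knn_graph(emb, 5L), seed = 2L)
  expect_setequal(unique(res$labels), 0:(res$n_clusters - 1L))
  expect_length(res$labels, 40L)
  sizes <- table(res$labels)
  expect_true(all(diff(as.integer(sizes)) <= 0) || res$n_clusters == 1L)
})

test_that("an exclusive gene is its cluster's top marker", {
  set.seed(6)
  counts <- matrix(rpois(40 * 20, 5), 40, 20)
  counts[1:20, 1] <- 60                  # gene 1 high only in cluster 0
  counts[21:40, 1] <- 0
  m <- cm(counts)
  norm <- normalize_log_cpm(m)
  clusters <- structure(list(labels = setNames(rep(0:1, each = 20),
                                               m$barcodes),
                             n_clusters = 2L, resolution = 1,
                             embedding = NULL, graph = NULL),
                        class = "ClusterResult")
  mk <- find_markers(norm, clusters)
  top <- mk[mk$cluster == 0, ][1, ]
  expect_equal(top$gene, "G01")
  expect_equal(top$frac_in, 1)
  expect_equal(top$frac_out, 0)
  expect_true(top$q <= top$p * nrow(mk) + 1e-12)
  expect_true(all(mk$q >= mk$p))

  # a gene identical in and out never passes the fold-change filter
  expect_false("G02" %in% mk$gene[mk$cluster == 0] &&
                 "G02" %in% mk$gene[mk$cluster == 1])
})

test_that("replicate consistency is 1 for duplicated regions and errors on overlap", {
  set.seed(10)
  block <- matrix(rpois(10 * 30, 5), 10, 30)
  m <- count_matrix(rbind(block, block), sprintf("S%02d", 1:20),
                    sprintf("G%02d", 1:30))
  r2 <- replicate_consistency(m, m$barcodes[1:10], m$barcodes[11:20])
  expect_equal(r2, 1)
  expect_error(replicate_consistency(m, m$barcodes[1:10], m$barcodes[10:20]),
               "overlap")
  expect_error(replicate_consistency(m, character(0), m$barcodes[1:2]),
               "non-empty")
})

test_that("within-domain consistency exceeds between-domain consistency", {
  spec <- tissue_spec(grid_width = 30L, grid_height = 20L, n_domains = 3L,
                      n_genes = 300L, n_modules = 9L, seed = 21L)
  sim <- simulate_tissue(spec)
  dom <- sim$truth$domain_of
  d0 <- names(dom)[dom == 0]
  d1 <- names(dom)[dom == 1]
  set.seed(1)
  half <- sample(d0, length(d0) %/% 2)
  within <- replicate_consistency(sim$matrix, half, setdiff(d0, half))
  between <- replicate_consistency(sim$matrix, d0, d1)
  expect_lt(between, within)
})
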