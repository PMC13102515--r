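mk_zprofile <- function(vals, genes) {
  cluster_profile(vals, genes, paste0("C", seq_len(ncol(vals)) - 1L))
}

mk_ann <- function(genes, tf, family = "TCP") {
  data.frame(gene_id = genes, symbol = genes, is_tf = genes %in% tf,
             tf_family = ifelse(genes %in% tf, family, ""),
             pathway_tags = "", term_ids = "", stringsAsFactors = FALSE)
}

mk_modules <- function(module_of) {
  structure(list(module_of = module_of, K = length(unique(module_of))),
            class = "ModuleAssignment")
}

hit_row <- function(gene, family, n = 1L) {
  data.frame(gene_id = rep(gene, n), family = rep(family, n),
             position = seq_len(n) - 1L, strand = rep("+", n),
             score = rep(1, n), stringsAsFactors = FALSE)
}

test_that("spatial consistency reproduces hand-computed correlations", {
  z <- mk_zprofile(rbind(c(1, 0, -1), c(1, 0, -1), c(-1, 0, 1)),
                   c("a", "b", "c"))
  expect_equal(spatial_consistency(z, "a", "b"), 1)
  expect_equal(spatial_consistency(z, "a", "c"), -1)

  z2 <- mk_zprofile(rbind(c(1, 2, 3, 4), c(2, 1, 4, 3)), c("a", "b"))
  expect_equal(spatial_consistency(z2, "a", "b"), 0.6)

  z3 <- mk_zprofile(rbind(c(0, 0, 0), c(1, 2, 3)), c("a", "b"))
  expect_true(is.na(spatial_consistency(z3, "a", "b")))
})

test_that("an edge demands both motif and spatial evidence", {
  genes <- c("tf", "t1")
  z <- mk_zprofile(rbind(c(1, 0, -1), c(1, 0, -1)), genes)
  ann <- mk_ann(genes, "tf")
  mods <- mk_modules(setNames(c(0L, 0L), genes))

  # perfect correlation and co-membership, but zero motif hits: no edge
  no_hits <- hit_row("t1", "TCP", 0L)
  net <- build_network(mods, z, no_hits, ann, targets = "t1")
  expect_equal(nrow(net$edges), 0L)

  # motif present, different modules, r = 0: no edge
  z2 <- mk_zprofile(rbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), genes)
  mods2 <- mk_modules(setNames(c(0L, 1L), genes))
  net2 <- build_network(mods2, z2, hit_row("t1", "TCP"), ann, targets = "t1")
  expect_equal(nrow(net2$edges), 0L)

  # both criteria met: edge with re-verifiable evidence
  net3 <- build_network(mods, z, hit_row("t1", "TCP", 2L), ann,
                        targets = "t1")
  expect_equal(nrow(net3$edges), 1L)
  expect_equal(net3$edges$motif_hits, 2L)
  expect_true(net3$edges$same_module)
  expect_equal(net3$edges$spatial_r, 1)

  # a constant-profile target is disqualified, not defaulted to r = 0
  zc <- mk_zprofile(rbind(c(1, 0, -1), c(0, 0, 0)), genes)
  modsx <- mk_modules(setNames(c(0L, 1L), genes))
  netc <- build_network(modsx, zc, hit_row("t1", "TCP"), ann, targets = "t1")
  expect_equal(nrow(netc$edges), 0L)

  expect_warning(net0 <- build_network(mods, z, no_hits, ann,
                                       targets = character(0)),
                 "empty target set")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("noise-free synthetic data yields a perfect network", {
  spec <- default_tissue_spec(seed = 11L)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  z <- expected_zprofile(spec)           # analytic, zero expression noise
  mods <- truth_modules(sim$truth)
  targets <- unique(unlist(spec$pathway_map))
  hits <- scan_promoters(prom$promoters[targets], prom$library,
                         rel_threshold = 1.0)
  net <- build_network(mods, z, hits, sim$annotation, targets)
  pr <- edge_precision_recall(net, sim$truth$true_edges)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
})

test_that("raising thresholds never adds edges", {
  spec <- default_tissue_spec(seed = 19L)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  z <- expected_zprofile(spec)
  mods <- truth_modules(sim$truth)
  targets <- unique(unlist(spec$pathway_map))
  edge_key <- function(net) paste(net$edges$tf_gene, net$edges$target_gene)
  prev_thr <- NULL
  for (thr in c(0.7, 0.85, 1.0)) {
    hits <- scan_promoters(prom$promoters[targets], prom$library, thr)
    for (rho in c(0.5, 0.8, 0.95)) {
      net <- build_network(mods, z, hits, sim$annotation, targets,
                           rho_min = rho)
      if (!is.null(prev_thr) && prev_thr$thr == thr) {
        expect_true(all(edge_key(net) %in% prev_thr$keys))
      }
      prev_thr <- list(thr = thr, keys = edge_key(net))
    }
  }
})

test_that("family connectivity counts distinct connected TF genes", {
  empty <- structure(list(edges = data.frame(tf_gene = character(0),
                                             tf_family = character(0),
                                             target_gene = character(0),
                                             same_module = logical(0),
                                             spatial_r = numeric(0),
                                             motif_hits = integer(0))),
                     class = "RegulatoryNetwork")
  expect_equal(nrow(family_connectivity(empty)), 0L)

  edges <- data.frame(
    tf_gene = c("b1", "b1", "b2", "m1"),
    tf_family = c("bHLH", "bHLH", "bHLH", "MYB"),
    target_gene = c("t1", "t2", "t1", "t3"),
    same_module = TRUE, spatial_r = 0.9, motif_hits = 1L,
    stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "RegulatoryNetwork")
  fc <- family_connectivity(net)
  expect_equal(fc$family, c("bHLH", "MYB"))
  expect_equal(fc$n_tfs, c(2L, 1L))
})

test_that("coregulator ranking favours multi-pathway coverage with a stable tie-break", {
  mk_net <- function(edges) structure(list(edges = edges),
                                      class = "RegulatoryNetwork")
  e1 <- data.frame(tf_gene = c("tfA", "tfB"), tf_family = "TCP",
                   target_gene = c("c1", "c2"), same_module = TRUE,
                   spatial_r = 0.9, motif_hits = 1L, stringsAsFactors = FALSE)
  e2 <- data.frame(tf_gene = "tfA", tf_family = "TCP", target_gene = "t1",
                   same_module = TRUE, spatial_r = 0.9, motif_hits = 1L,
                   stringsAsFactors = FALSE)
  rk <- rank_coregulators(list(cat = mk_net(e1), thea = mk_net(e2)),
                          mk_ann(c("tfA", "tfB"), c("tfA", "tfB")))
  expect_equal(rk$tf_gene[1], "tfA")
  expect_equal(rk$sets_covered, c(2L, 1L))

  # identical evidence: deterministic gene-id tie-break
  e3 <- data.frame(tf_gene = c("tfZ", "tfC"), tf_family = "TCP",
                   target_gene = c("c1", "c2"), same_module = TRUE,
                   spatial_r = 0.8, motif_hits = 1L, stringsAsFactors = FALSE)
  e4 <- data.frame(tf_gene = c("tfZ", "tfC"), tf_family = "TCP",
                   target_gene = c("t1", "t2"), same_module = TRUE,
                   spatial_r = 0.8, motif_hits = 1L, stringsAsFactors = FALSE)
  rk2 <- rank_coregulators(list(cat = mk_net(e3), thea = mk_net(e4)),
                           mk_ann(c("tfC", "tfZ"), c("tfC", "tfZ")))
  expect_equal(rk2$tf_gene, c("tfC", "tfZ"))

  expect_warning(
    rk0 <- rank_coregulators(list(a = mk_net(e1[0, ]), b = mk_net(e2[0, ])),
                             mk_ann("tfA", "tfA")),
    "no TF")
  expect_equal(nrow(rk0), 0L)
})

test_that("GraphML export round-trips the edge structure", {
  edges <- data.frame(tf_gene = c("tfA", "tfA"), tf_family = "TCP",
                      target_gene = c("t1", "t2"), same_module = TRUE,
                      spatial_r = c(0.9, 0.85), motif_hits = 1:2,
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges), class = "RegulatoryNetwork")
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::V(g)$name, c("tfA", "t1", "t2"))
  expect_setequal(igraph::E(g)$motif_hits, 1:2)
})

test_that("every edge's evidence re-verifies from its inputs", {
  spec <- default_tissue_spec(seed = 23L)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  z <- expected_zprofile(spec)
  mods <- truth_modules(sim$truth)
  targets <- unique(unlist(spec$pathway_map))
  hits <- scan_promoters(prom$promoters[targets], prom$library, 0.85)
  net <- build_network(mods, z, hits, sim$annotation, targets)
  expect_gt(nrow(net$edges), 0L)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    expect_gte(e$motif_hits, 1L)
    expect_equal(e$motif_hits,
                 sum(hits$gene_id == e$target_gene & hits$family == e$tf_family))
    expect_equal(e$spatial_r, spatial_consistency(z, e$tf_gene, e$target_gene))
    expect_true(e$same_module ||
                  (!is.na(e$spatial_r) && e$spatial_r >= net$parameters$rho_min))
  }
})
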