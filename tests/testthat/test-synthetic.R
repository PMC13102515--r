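small_spec <- function(seed = 1L, ...) {
  tissue_spec(grid_width = 12L, grid_height = 6L, n_domains = 3L,
              n_genes = 45L, n_modules = 9L, n_tfs = 0L, seed = seed, ...)
}

test_that("simulate_tissue is bit-identical at a fixed seed", {
  spec <- small_spec(42L)
  a <- simulate_tissue(spec)
  b <- simulate_tissue(spec)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth, b$truth)
  c <- simulate_tissue(spec, seed = 43L)
  expect_false(identical(as.matrix(a$matrix$counts),
                         as.matrix(c$matrix$counts)))
})

test_that("a one-domain spec with unit activity is homogeneous", {
  spec <- tissue_spec(grid_width = 10L, grid_height = 5L, n_domains = 1L,
                      n_genes = 20L, n_modules = 2L, seed = 1L)
  expect_true(all(spec$module_activity == 1))
  sim <- simulate_tissue(spec)
  expect_equal(unique(unname(sim$truth$domain_of)), 0L)
})

test_that("generator errors on degenerate specifications", {
  expect_error(tissue_spec(n_modules = 10L, n_genes = 5L), "exceeds")
  expect_error(tissue_spec(grid_width = 0L), "positive")
  expect_error(tissue_spec(promoter_len = 4L, motif_width = 8L), "shorter")
  expect_error(tissue_spec(n_genes = 10L, n_modules = 2L, n_domains = 2L,
                           module_activity = matrix(c(-1, 1, 1, 1), 2, 2)),
               ">= 0")
})

test_that("empirical NB means track the specified means", {
  # 2000 spots, fixed base mean 50, no library-size variation
  ok <- 0L
  for (s in 1:20) {
    spec <- tissue_spec(grid_width = 50L, grid_height = 40L, n_domains = 1L,
                        n_genes = 5L, n_modules = 1L, base_mean = 50,
                        libsize_sigma = 0, seed = s)
    sim <- simulate_tissue(spec)
    means <- Matrix::colMeans(sim$matrix$counts)
    ok <- ok + sum(abs(means - 50) / 50 < 0.05)
  }
  expect_gte(ok / (20 * 5), 0.95)
})

test_that("counts are over-dispersed relative to Poisson", {
  spec <- tissue_spec(grid_width = 25L, grid_height = 20L, n_domains = 1L,
                      n_genes = 30L, n_modules = 1L, base_mean = 20,
                      libsize_sigma = 0, nb_dispersion = 2, seed = 5L)
  sim <- simulate_tissue(spec)
  m <- Matrix::colMeans(sim$matrix$counts)
  v <- apply(as.matrix(sim$matrix$counts), 2, var)
  expect_true(all(v >= m))   # 500 draws per gene, mu^2/size margin is wide
})

test_that("every planted site survives in its target promoter", {
  spec <- default_tissue_spec(seed = 7L)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  fam_of <- setNames(sim$annotation$tf_family, sim$annotation$gene_id)
  for (i in seq_len(nrow(sim$truth$true_edges))) {
    tg <- sim$truth$true_edges$target_gene[i]
    fam <- fam_of[[sim$truth$true_edges$tf_gene[i]]]
    cons <- pwm_consensus(prom$library[[fam]])
    seq <- prom$promoters[[tg]]
    expect_true(grepl(cons, seq, fixed = TRUE) ||
                  grepl(reverse_complement(cons), seq, fixed = TRUE),
                label = sprintf("consensus of %s in promoter of %s", fam, tg))
  }
  expect_equal(nrow(prom$planted_sites), nrow(sim$truth$true_edges))
})

test_that("no edges means no planted sites; minimal promoters pin the site", {
  spec <- small_spec(3L)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  expect_equal(nrow(prom$planted_sites), 0L)

  spec2 <- tissue_spec(grid_width = 5L, grid_height = 4L, n_domains = 1L,
                       n_genes = 10L, n_modules = 1L, n_tfs = 1L,
                       tf_module_map = 0L, tf_families = "TCP",
                       target_map = list(G0010 = "G0001"),
                       promoter_len = 8L, motif_width = 8L, seed = 2L)
  sim2 <- simulate_tissue(spec2)
  prom2 <- simulate_promoters(sim2$truth, spec2, sim2$annotation)
  expect_equal(prom2$planted_sites$position, 0L)
  cons <- pwm_consensus(prom2$library$TCP)
  expect_true(prom2$promoters[["G0001"]] %in%
                c(cons, reverse_complement(cons)))
})

test_that("knockdown generator reproduces the designed shifts", {
  spec <- default_tissue_spec(seed = 9L)
  sim <- simulate_tissue(spec)

  # near-unit delta: no between-condition difference up to tiny noise
  kd0 <- simulate_knockdown(sim$truth, spec, n_reps = 4L, delta = 1 - 1e-9,
                            noise_sd = 1e-9, seed = 1L)
  tf <- names(sort(table(sim$truth$true_edges$tf_gene), decreasing = TRUE))[1]
  diff0 <- mean(kd0[[tf]][kd0$condition == "control"]) -
    mean(kd0[[tf]][kd0$condition == "knockdown"])
  expect_lt(abs(diff0), 1e-6)

  # strong knockdown, low noise: every replicate of a positive target drops
  kd <- simulate_knockdown(sim$truth, spec, n_reps = 6L, delta = 0.2,
                           beta = 1, noise_sd = 0.1, seed = 2L)
  tg <- sim$truth$true_edges$target_gene[sim$truth$true_edges$tf_gene == tf][1]
  expect_true(max(kd[[tg]][kd$condition == "knockdown"]) <
                min(kd[[tg]][kd$condition == "control"]))

  # fixed seed reproducibility
  expect_identical(kd, simulate_knockdown(sim$truth, spec, n_reps = 6L,
                                          delta = 0.2, beta = 1,
                                          noise_sd = 0.1, seed = 2L))
  expect_error(simulate_knockdown(sim$truth, spec, delta = 1.2), "delta")
  expect_error(simulate_knockdown(sim$truth, spec, n_reps = 1L), "n_reps")
})
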