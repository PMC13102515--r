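default_params <- function() {
  list(min_counts_per_spot = 100, min_spots_per_gene = 3,
       scale_factor = 1e4, n_hvg = 2000L, n_pcs = 30L, knn_k = 15L,
       resolution = 1.0, target_clusters = NULL,
       K = 9L, min_expr = 0.1, clamp = NULL,
       rel_threshold = 0.85, rho_min = 0.8, require_module = FALSE,
       min_frac_in = 0.1, min_log2fc = 0.25)
}

#' Run the full analysis in memory
#'
#' Composes the stages qc, normalize, pca, knn, louvain, markers,
#' pseudobulk, filter, standardize, kmeans, scan, network, rank, enrich
#' on already-loaded inputs. Each stage failure is re-raised with the
#' stage named.
#'
#' @param matrix a [count_matrix()].
#' @param geometry spot geometry (carried through, not used by the
#'   expression stages).
#' @param annotation gene annotation.
#' @param promoters named character vector of promoter sequences.
#' @param library named PWM list.
#' @param params named list of stage parameters; missing entries fall
#'   back to the package defaults.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return list with every intermediate and final object (`clusters`,
#'   `markers`, `modules`, `zprofile`, `hits`, `networks`, `ranking`,
#'   `enrichment`, ...).
#' @export
run_stages <- function(matrix, geometry, annotation, promoters, library,
                       params = list(), seed = 1L) {
  p <- utils::modifyList(default_params(), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s': %s", name, conditionMessage(e))
    })
  }
  out <- list(params = p, seed = seed)
  out$qc <- stage("qc", qc_filter(matrix, p$min_counts_per_spot,
                                  p$min_spots_per_gene))
  out$norm <- stage("normalize", normalize_log_cpm(out$qc, p$scale_factor))
  hvg <- stage("pca", highly_variable_genes(out$norm, p$n_hvg))
  out$embedding <- stage("pca", run_pca(out$norm, n_pcs = p$n_pcs,
                                        genes = hvg))
  out$graph <- stage("knn", build_knn_graph(out$embedding, k = p$knn_k))
  out$clusters <- stage("louvain", {
    if (!is.null(p$target_clusters)) {
      sweep_resolution(out$graph, p$target_clusters, seed = seed)
    } else {
      louvain_cluster(out$graph, resolution = p$resolution, seed = seed)
    }
  })
  out$markers <- stage("markers",
    if (out$clusters$n_clusters >= 2L) {
      find_markers(out$norm, out$clusters, p$min_frac_in, p$min_log2fc)
    } else {
      NULL
    })
  out$profile <- stage("pseudobulk", pseudobulk(out$norm, out$clusters))
  out$profile_kept <- stage("filter",
                            filter_low_expression(out$profile, p$min_expr))
  out$zprofile <- stage("standardize",
                        standardize_profile(out$profile_kept, p$clamp))
  out$modules <- stage("kmeans",
                       kmeans_modules(out$zprofile, K = p$K, seed = seed))
  pathway_tags <- sort(unique(unlist(
    strsplit(annotation$pathway_tags, ";", fixed = TRUE))))
  pathway_tags <- pathway_tags[pathway_tags != ""]
  structural <- unique(unlist(lapply(pathway_tags, function(tag) {
    annotation_genes_with_tag(annotation, tag)
  })))
  out$hits <- stage("scan", {
    if (is.null(promoters) || is.null(library)) {
      stopf("promoters and motif library are required")
    }
    scan_promoters(promoters[intersect(structural, names(promoters))],
                   library, p$rel_threshold)
  })
  out$networks <- stage("network", {
    nets <- lapply(pathway_tags, function(tag) {
      targets <- intersect(annotation_genes_with_tag(annotation, tag),
                           out$zprofile$gene_ids)
      build_network(out$modules, out$zprofile, out$hits, annotation,
                    targets, rho_min = p$rho_min,
                    require_module = p$require_module)
    })
    stats::setNames(nets, pathway_tags)
  })
  out$ranking <- stage("rank",
    if (length(out$networks) >= 2L) {
      rank_coregulators(out$networks, annotation)
    } else {
      NULL
    })
  out$enrichment <- stage("enrich", {
    universe <- out$zprofile$gene_ids
    res <- lapply(0:(out$modules$K - 1L), function(m) {
      genes <- names(out$modules$module_of)[out$modules$module_of == m]
      if (!length(genes)) return(NULL)
      e <- term_enrichment(genes, annotation, universe)
      if (nrow(e)) e$module <- m
      e
    })
    do.call(rbind, Filter(function(x) !is.null(x) && nrow(x), res))
  })
  out
}

#' Run the pipeline from a config and write its artifacts
#'
#' The config (a named list, or the path of a YAML file holding one)
#' names the inputs (`counts_dir`, `positions_csv`, `annotation_tsv`,
#' `promoters_fasta`, `motifs_meme`), the output directory `out_dir`,
#' a `seed`, and optional `params` overriding the stage defaults.
#' Arguments in `override` take precedence over the config file. Tables
#' are written as TSV under `out_dir` together with a `manifest.json`
#' recording parameters and seed.
#'
#' @param config named list or YAML path.
#' @param override named list of config entries taking precedence.
#' @return the [run_stages()] result, invisibly, with `$report` attached.
#' @export
run_pipeline <- function(config, override = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, override)
  for (f in c("counts_dir", "positions_csv", "annotation_tsv",
              "promoters_fasta", "motifs_meme", "out_dir")) {
    if (is.null(config[[f]])) stopf("config entry '%s' is required", f)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  matrix <- read_count_matrix(config$counts_dir)
  geometry <- read_spot_positions(config$positions_csv, matrix$barcodes)
  annotation <- read_gene_annotation(config$annotation_tsv)
  promoters <- read_promoters(config$promoters_fasta)
  if (!file.exists(config$motifs_meme)) {
    stopf("stage 'scan': motif file '%s' not found", config$motifs_meme)
  }
  library <- read_motifs(config$motifs_meme)
  res <- run_stages(matrix, geometry, annotation, promoters, library,
                    params = if (is.null(config$params)) list() else config$params,
                    seed = seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wtsv(data.frame(barcode = names(res$clusters$labels),
                  cluster = unname(res$clusters$labels)), "clusters.tsv")
  if (!is.null(res$markers)) wtsv(res$markers, "markers.tsv")
  wtsv(data.frame(gene_id = names(res$modules$module_of),
                  module = unname(res$modules$module_of)), "modules.tsv")
  wtsv(as.data.frame(res$zprofile$values), "profile.tsv")
  wtsv(res$hits, "hits.tsv")
  for (nm in names(res$networks)) {
    wtsv(res$networks[[nm]]$edges, sprintf("edges_%s.tsv", nm))
    wtsv(family_connectivity(res$networks[[nm]]),
         sprintf("family_counts_%s.tsv", nm))
    if (nrow(res$networks[[nm]]$edges)) {
      write_network_graphml(res$networks[[nm]],
                            file.path(config$out_dir,
                                      sprintf("network_%s.graphml", nm)))
    }
  }
  if (!is.null(res$ranking)) wtsv(res$ranking, "ranking.tsv")
  if (!is.null(res$enrichment)) wtsv(res$enrichment, "enrichment.tsv")
  res$report <- list(seed = seed, params = res$params,
                     n_spots = nrow(res$qc$counts),
                     n_genes = ncol(res$qc$counts),
                     n_clusters = res$clusters$n_clusters)
  jsonlite::write_json(res$report, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(res)
}

#' Self-validating demonstration run
#'
#' Simulates the default study conditions (three band domains, nine
#' modules, one planted dual-pathway TCP regulator), runs the full
#' pipeline, and reports how well the ground truth was recovered: the
#' adjusted Rand index of spot clusters against planted domains, K-means
#' module purity against planted modules, and the rank of the planted
#' dual-pathway TF in the coregulator screen.
#'
#' @param seed integer seed driving both the simulation and the analysis.
#' @param params stage-parameter overrides.
#' @param spec optional [tissue_spec()]; default [default_tissue_spec()].
#' @return list with `domain_ari`, `module_purity`, `planted_tf`,
#'   `planted_tf_rank`, `n_clusters`, plus the full `run_stages()` result
#'   under `$stages`.
#' @export
run_demo <- function(seed = 1L, params = list(), spec = NULL) {
  if (is.null(spec)) spec <- default_tissue_spec(seed = seed)
  sim <- simulate_tissue(spec)
  prom <- simulate_promoters(sim$truth, spec, sim$annotation)
  res <- run_stages(sim$matrix, sim$geometry, sim$annotation,
                    prom$promoters, prom$library, params = params,
                    seed = seed)
  labels <- res$clusters$labels
  ari <- mclust::adjustedRandIndex(labels,
                                   sim$truth$domain_of[names(labels)])
  purity <- module_purity(res$modules, sim$truth$module_of)
  planted <- if (nrow(sim$truth$true_edges)) {
    names(sort(table(sim$truth$true_edges$tf_gene), decreasing = TRUE))[1]
  } else {
    NA_character_
  }
  rank_ <- if (!is.null(res$ranking) && planted %in% res$ranking$tf_gene) {
    res$ranking$rank[res$ranking$tf_gene == planted]
  } else {
    NA_integer_
  }
  list(domain_ari = ari, module_purity = purity, planted_tf = planted,
       planted_tf_rank = rank_, n_clusters = res$clusters$n_clusters,
       stages = res)
}
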