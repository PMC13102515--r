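#' Spatial expression consistency of two genes
#'
#' Pearson correlation of the two genes' standardized cluster profiles —
#' the quantitative reading of "shared spatial expression pattern".
#' Constant profiles have no defined correlation and return `NA`, which
#' disqualifies the pair from network edges.
#'
#' @param zprofile standardized [cluster_profile()] with >= 3 clusters.
#' @param gene_a,gene_b gene ids present in the profile.
#' @return Pearson r, or `NA` when either profile is constant.
#' @export
spatial_consistency <- function(zprofile, gene_a, gene_b) {
  if (ncol(zprofile$values) < 3L) stopf("need >= 3 clusters for a meaningful r")
  if (!all(c(gene_a, gene_b) %in% zprofile$gene_ids)) {
    stopf("gene absent from profile")
  }
  a <- zprofile$values[gene_a, ]
  b <- zprofile$values[gene_b, ]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Build the dual-criterion TF-target regulatory network
#'
#' An edge TF -> target requires BOTH lines of evidence: (i) at least one
#' binding-site hit of the TF's family in the target's promoter, and (ii)
#' spatial expression consistency — shared K-means module, or Pearson
#' r >= `rho_min` over standardized cluster profiles (co-membership alone
#' suffices unless `require_module` additionally demands it). Evidence is
#' recorded per edge so every edge can be re-verified from its inputs.
#' `use_motif` / `use_spatial` switch either criterion off for ablation
#' experiments only.
#'
#' @param modules a `ModuleAssignment`.
#' @param zprofile standardized [cluster_profile()].
#' @param hits a `MotifHitTable` from [scan_promoters()].
#' @param annotation gene annotation (supplies `is_tf` and `tf_family`).
#' @param targets character vector of candidate target genes (the
#'   structural-gene set of a pathway).
#' @param rho_min spatial-correlation threshold.
#' @param require_module if `TRUE`, module co-membership is mandatory and
#'   the correlation is additional evidence only.
#' @param use_motif,use_spatial ablation switches (keep `TRUE` for real
#'   analyses).
#' @return list of class `RegulatoryNetwork`: `edges` (data.frame
#'   `tf_gene`, `tf_family`, `target_gene`, `same_module`, `spatial_r`,
#'   `motif_hits`) and `parameters`.
#' @export
build_network <- function(modules, zprofile, hits, annotation, targets,
                          rho_min = 0.8, require_module = FALSE,
                          use_motif = TRUE, use_spatial = TRUE) {
  if (!length(targets)) {
    warnf("empty target set: empty network")
  }
  if (!all(targets %in% zprofile$gene_ids)) {
    stopf("target '%s' absent from the profile",
          setdiff(targets, zprofile$gene_ids)[1])
  }
  tfs <- annotation$gene_id[annotation$is_tf]
  tfs <- intersect(tfs, zprofile$gene_ids)
  fam_of <- stats::setNames(annotation$tf_family, annotation$gene_id)
  hit_counts <- if (nrow(hits)) {
    stats::aggregate(list(n = hits$position),
                     by = list(gene_id = hits$gene_id, family = hits$family),
                     FUN = length)
  } else {
    data.frame(gene_id = character(0), family = character(0), n = integer(0))
  }
  rows <- list()
  for (tf in tfs) {
    fam <- fam_of[[tf]]
    for (tg in setdiff(targets, tf)) {
      nhit <- hit_counts$n[hit_counts$gene_id == tg & hit_counts$family == fam]
      nhit <- if (length(nhit)) nhit else 0L
      if (use_motif && nhit < 1L) next
      same_mod <- !is.na(modules$module_of[tf]) &&
        !is.na(modules$module_of[tg]) &&
        modules$module_of[[tf]] == modules$module_of[[tg]]
      r <- spatial_consistency(zprofile, tf, tg)
      if (use_spatial) {
        spatial_ok <- if (require_module) {
          same_mod
        } else {
          same_mod || (!is.na(r) && r >= rho_min)
        }
        if (!spatial_ok) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf_gene = tf, tf_family = fam, target_gene = tg,
        same_module = same_mod, spatial_r = r, motif_hits = as.integer(nhit),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) {
    e <- do.call(rbind, rows)
    e <- e[order(e$tf_gene, e$target_gene), , drop = FALSE]
    rownames(e) <- NULL
    e
  } else {
    data.frame(tf_gene = character(0), tf_family = character(0),
               target_gene = character(0), same_module = logical(0),
               spatial_r = numeric(0), motif_hits = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(edges = edges,
                 parameters = list(rho_min = rho_min,
                                   require_module = require_module,
                                   use_motif = use_motif,
                                   use_spatial = use_spatial)),
            class = "RegulatoryNetwork")
}

#' Precision and recall of a network against planted edges
#'
#' @param network a `RegulatoryNetwork`.
#' @param true_edges data.frame with `tf_gene`, `target_gene`.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn` (precision is
#'   `NA` for an empty network).
#' @export
edge_precision_recall <- function(network, true_edges) {
  pred <- paste(network$edges$tf_gene, network$edges$target_gene)
  truth <- paste(true_edges$tf_gene, true_edges$target_gene)
  tp <- sum(pred %in% truth)
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       tp = tp, fp = length(pred) - tp, fn = length(truth) - tp)
}

#' Family connectivity summary
#'
#' Number of distinct TF genes with at least one edge, per TF family —
#' the per-family member counts annotated on the pathway networks.
#' Families with no connected TF are omitted.
#'
#' @param network a `RegulatoryNetwork`.
#' @return data.frame `family`, `n_tfs`, sorted by decreasing count.
#' @export
family_connectivity <- function(network) {
  if (!nrow(network$edges)) {
    return(data.frame(family = character(0), n_tfs = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- tapply(network$edges$tf_gene, network$edges$tf_family,
                function(g) length(unique(g)))
  out <- data.frame(family = names(tab), n_tfs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_tfs, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a regulatory network as GraphML
#'
#' Writes a directed TF -> target graph with the evidence fields
#' (`tf_family`, `same_module`, `spatial_r`, `motif_hits`) as edge
#' attributes, for use in Cytoscape/Gephi-style viewers.
#'
#' @param network a `RegulatoryNetwork`.
#' @param path output file path.
#' @export
write_network_graphml <- function(network, path) {
  e <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$tf_gene, to = e$target_gene,
               tf_family = e$tf_family, same_module = e$same_module,
               spatial_r = e$spatial_r, motif_hits = e$motif_hits,
               stringsAsFactors = FALSE),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(NULL)
}

#' Rank TFs as candidate coregulators across pathway gene sets
#'
#' Builds on one network per pathway set and scores each TF by (i) the
#' number of pathway sets it has at least one edge into, (ii) its total
#' distinct targets, (iii) the mean spatial correlation over its edges —
#' compared lexicographically, with the gene id as a deterministic
#' tie-break. A TF connected into several metabolite pathways at once is
#' the screen's candidate coregulator.
#'
#' @param networks named list of `RegulatoryNetwork`, one per pathway set
#'   (>= 2).
#' @param annotation gene annotation.
#' @return data.frame `tf_gene`, `tf_family`, `sets_covered`,
#'   `targets_covered`, `mean_spatial_r`, `rank`; empty with a warning
#'   when no TF has an edge.
#' @export
rank_coregulators <- function(networks, annotation) {
  if (length(networks) < 2L) stopf("need >= 2 pathway networks to rank")
  all_edges <- do.call(rbind, lapply(names(networks), function(nm) {
    e <- networks[[nm]]$edges
    if (nrow(e)) e$pathway_set <- nm
    e
  }))
  if (is.null(all_edges) || !nrow(all_edges)) {
    warnf("no TF with any edge: empty ranking")
    return(data.frame(tf_gene = character(0), tf_family = character(0),
                      sets_covered = integer(0), targets_covered = integer(0),
                      mean_spatial_r = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  tfs <- unique(all_edges$tf_gene)
  rows <- lapply(tfs, function(tf) {
    e <- all_edges[all_edges$tf_gene == tf, , drop = FALSE]
    data.frame(tf_gene = tf, tf_family = e$tf_family[1],
               sets_covered = length(unique(e$pathway_set)),
               targets_covered = length(unique(e$target_gene)),
               mean_spatial_r = mean(e$spatial_r, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$sets_covered, -out$targets_covered, -out$mean_spatial_r,
               out$tf_gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
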