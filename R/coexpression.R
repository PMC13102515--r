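#' Per-cluster pseudo-bulk expression profile
#'
#' @param values genes x clusters numeric matrix.
#' @param gene_ids,cluster_ids dimension identifiers.
#' @return list of class `ClusterProfile`.
#' @export
cluster_profile <- function(values, gene_ids, cluster_ids) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cluster_ids)) {
    stopf("profile dimensions do not match identifiers")
  }
  if (any(!is.finite(values))) stopf("profile values must be finite")
  dimnames(values) <- list(gene_ids, cluster_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 cluster_ids = as.character(cluster_ids)),
            class = "ClusterProfile")
}

#' Collapse spots to per-cluster mean profiles
#'
#' `values[g, c]` is the mean normalized expression of gene g over the
#' spots of cluster c — the genes x clusters matrix behind the spatial
#' expression heatmaps and the K-means grouping.
#'
#' @param norm a [normalize_log_cpm()] result.
#' @param clusters a `ClusterResult` labelling every spot of `norm`.
#' @return a [cluster_profile()].
#' @export
pseudobulk <- function(norm, clusters) {
  labels <- clusters$labels[norm$barcodes]
  if (anyNA(labels)) stopf("every spot must carry a cluster label")
  ids <- sort(unique(labels))
  prof <- vapply(ids, function(cl) {
    colMeans(norm$values[labels == cl, , drop = FALSE])
  }, numeric(ncol(norm$values)))
  cluster_profile(prof, norm$gene_ids, paste0("C", ids))
}

#' Drop genes with low pseudo-bulk expression
#'
#' Retains gene g iff `max_c values[g, c] >= min_max_value` (inclusive).
#'
#' @param profile a [cluster_profile()].
#' @param min_max_value threshold on the per-gene maximum (>= 0).
#' @return filtered [cluster_profile()].
#' @export
filter_low_expression <- function(profile, min_max_value = 0.1) {
  if (min_max_value < 0) stopf("min_max_value must be >= 0")
  keep <- apply(profile$values, 1, max) >= min_max_value
  if (!any(keep)) stopf("no genes retained by the expression filter")
  cluster_profile(profile$values[keep, , drop = FALSE],
                  profile$gene_ids[keep], profile$cluster_ids)
}

#' Standardize profiles gene-wise
#'
#' Per gene: subtract the row mean and divide by the sample standard
#' deviation (ddof 1). Constant rows become all zeros with a warning so
#' module indices stay aligned with the annotation. With `clamp = c`
#' values are truncated to `[-c, c]` after scaling.
#'
#' @param profile a [cluster_profile()] with >= 2 clusters.
#' @param clamp optional symmetric truncation bound (`NULL` = off).
#' @return standardized [cluster_profile()].
#' @export
standardize_profile <- function(profile, clamp = NULL) {
  if (ncol(profile$values) < 2L) stopf("standardization needs >= 2 clusters")
  mu <- rowMeans(profile$values)
  sd_ <- apply(profile$values, 1, stats::sd)
  const <- sd_ == 0
  if (any(const)) {
    warnf("%d constant gene profile(s) standardized to all zeros", sum(const))
    sd_[const] <- 1
  }
  z <- (profile$values - mu) / sd_
  z[const, ] <- 0
  if (!is.null(clamp)) {
    if (clamp <= 0) stopf("clamp must be positive")
    z <- pmin(pmax(z, -clamp), clamp)
  }
  cluster_profile(z, profile$gene_ids, profile$cluster_ids)
}

# k-means++ initial centres; probability of each point proportional to its
# squared distance from the nearest centre already chosen
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# One Lloyd run. Nearest-centroid ties break to the lowest module index;
# a cluster emptied during iteration is reseeded from the point farthest
# from its centroid.
lloyd_once <- function(x, centers, max_iter = 100L, tol = 1e-10) {
  k <- nrow(centers)
  assign_pts <- function(centers) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_pts(centers)
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      pts <- which(lab == j)
      if (!length(pts)) {
        d2all <- rowSums((x - centers[lab, , drop = FALSE])^2)
        far <- which.max(d2all)
        centers[j, ] <- x[far, ]
        lab[far] <- j
        pts <- far
      }
      centers[j, ] <- colMeans(x[pts, , drop = FALSE])
    }
    lab_new <- assign_pts(centers)
    new_inertia <- sum((x - centers[lab_new, , drop = FALSE])^2)
    if (identical(lab_new, lab) || inertia - new_inertia < tol) {
      lab <- lab_new
      inertia <- new_inertia
      break
    }
    lab <- lab_new
    inertia <- new_inertia
  }
  list(labels = lab, centers = centers, inertia = inertia)
}

#' K-means coexpression modules
#'
#' Groups standardized gene profiles into K modules with Lloyd's
#' algorithm, k-means++ initialization, and the best of `n_init` restarts
#' by within-module sum of squares. Deterministic at a fixed seed.
#'
#' @param zprofile standardized [cluster_profile()].
#' @param K number of modules (the reference configuration uses K = 9).
#' @param seed integer seed.
#' @param n_init random restarts.
#' @return list of class `ModuleAssignment`: `module_of` (named 0-based
#'   integer vector), `K`, `centroids` (K x clusters), `inertia`, `seed`.
#' @export
kmeans_modules <- function(zprofile, K = 9L, seed = 1L, n_init = 10L) {
  x <- zprofile$values
  if (K > nrow(x)) stopf("K (%d) exceeds the number of genes (%d)", K, nrow(x))
  best <- with_seed(derive_seed(seed, 53L), {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- lloyd_once(x, kmeanspp_init(x, K))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best
  })
  centroids <- best$centers
  rownames(centroids) <- paste0("M", seq_len(K) - 1L)
  colnames(centroids) <- zprofile$cluster_ids
  structure(list(module_of = stats::setNames(best$labels - 1L,
                                             zprofile$gene_ids),
                 K = as.integer(K), centroids = centroids,
                 inertia = best$inertia, seed = as.integer(seed)),
            class = "ModuleAssignment")
}

#' Purity of a module assignment against planted modules
#'
#' For each inferred module, the fraction of its genes belonging to the
#' best-matching planted module, averaged over genes.
#'
#' @param modules a `ModuleAssignment`.
#' @param truth_module_of named integer vector of planted module labels.
#' @return purity in [0, 1].
#' @export
module_purity <- function(modules, truth_module_of) {
  genes <- names(modules$module_of)
  tab <- table(modules$module_of, truth_module_of[genes])
  sum(apply(tab, 1, max)) / length(genes)
}
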