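#' Specification of a synthetic tissue section
#'
#' Describes the generative model behind [simulate_tissue()]: a
#' `grid_width` x `grid_height` spot lattice partitioned into
#' `n_domains` tissue domains, genes grouped into `n_modules`
#' coexpression modules, and negative-binomial UMI counts whose means are
#' `lib_s * base_mean_g * module_activity[module(g), domain(s)]` with a
#' log-normal per-spot library factor. TF genes are ordinary module
#' members flagged `is_tf`; their regulatory targets and the motif sites
#' planted in target promoters are recorded as ground truth.
#'
#' @param grid_width,grid_height lattice dimensions (spots =
#'   `grid_width * grid_height`).
#' @param n_domains number of tissue domains.
#' @param domain_layout `"bands"` (axis-aligned vertical bands, the
#'   deterministic default) or `"voronoi"` (random seed points).
#' @param n_genes total genes, TFs included.
#' @param n_modules number of coexpression modules.
#' @param module_activity `n_modules` x `n_domains` matrix of non-negative
#'   fold-activations; `NULL` uses [default_module_activity()].
#' @param base_mean per-gene baseline mean counts; `NULL` draws log-normal
#'   (meanlog `log(2)`, sdlog 1) means at simulation time; a scalar is
#'   recycled.
#' @param nb_dispersion negative-binomial size parameter shared by all
#'   genes (smaller = more over-dispersed).
#' @param libsize_sigma log-normal sd of the per-spot library factor.
#' @param n_tfs number of TF genes (the last `n_tfs` genes).
#' @param tf_module_map integer vector (one per TF, values in
#'   `0:(n_modules-1)`) giving each TF's module; `NULL` spreads TFs round
#'   robin.
#' @param tf_families character vector of family names, one per TF.
#' @param target_map named list: TF gene id -> character vector of target
#'   gene ids (targets must sit in the TF's module for the spatial signal
#'   to be real).
#' @param pathway_map named list: pathway tag -> character vector of gene
#'   ids (the structural-gene sets handed to the network stage).
#' @param promoter_len promoter length in bp.
#' @param motif_width planted motif width in bp.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a `tissue_spec` list.
#' @export
tissue_spec <- function(grid_width = 50L, grid_height = 30L, n_domains = 3L,
                        domain_layout = c("bands", "voronoi"),
                        n_genes = 900L, n_modules = 9L,
                        module_activity = NULL, base_mean = NULL,
                        nb_dispersion = 2, libsize_sigma = 0.3,
                        n_tfs = 0L, tf_module_map = NULL,
                        tf_families = NULL, target_map = list(),
                        pathway_map = list(),
                        promoter_len = 500L, motif_width = 8L, seed = 1L) {
  domain_layout <- match.arg(domain_layout)
  if (grid_width < 1L || grid_height < 1L) stopf("grid dimensions must be positive")
  if (n_modules < 1L) stopf("n_modules must be >= 1")
  if (n_modules > n_genes) stopf("n_modules (%d) exceeds n_genes (%d)",
                                 n_modules, n_genes)
  if (n_tfs > n_genes) stopf("more TFs than genes")
  if (is.null(module_activity)) {
    module_activity <- default_module_activity(n_modules, n_domains)
  }
  module_activity <- as.matrix(module_activity)
  if (!all(dim(module_activity) == c(n_modules, n_domains))) {
    stopf("module_activity must be %d x %d", n_modules, n_domains)
  }
  if (any(module_activity < 0)) stopf("module_activity entries must be >= 0")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (n_tfs > 0L) {
    if (is.null(tf_module_map)) tf_module_map <- (seq_len(n_tfs) - 1L) %% n_modules
    if (is.null(tf_families)) tf_families <- paste0("FAM", seq_len(n_tfs))
    if (length(tf_module_map) != n_tfs || length(tf_families) != n_tfs) {
      stopf("tf_module_map and tf_families must have one entry per TF")
    }
    if (any(tf_module_map < 0 | tf_module_map >= n_modules)) {
      stopf("tf_module_map values must be in 0..%d", n_modules - 1L)
    }
  }
  if (promoter_len < motif_width) {
    stopf("promoter_len (%d) shorter than motif_width (%d)", promoter_len,
          motif_width)
  }
  structure(list(grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 n_domains = as.integer(n_domains),
                 domain_layout = domain_layout,
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 module_activity = module_activity,
                 base_mean = base_mean,
                 nb_dispersion = nb_dispersion,
                 libsize_sigma = libsize_sigma,
                 n_tfs = as.integer(n_tfs),
                 tf_module_map = tf_module_map,
                 tf_families = tf_families,
                 target_map = target_map,
                 pathway_map = pathway_map,
                 promoter_len = as.integer(promoter_len),
                 motif_width = as.integer(motif_width),
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Default module activity profiles
#'
#' Places the `n_modules` modules at equally spaced angles on the circle
#' of standardized profiles over `n_domains` domains:
#' `activity[m, d] = exp(a * cos(2*pi*m/M - 2*pi*d/D))` with `a` chosen so
#' that every module's max/min activity ratio is at least `contrast`.
#' With three domains adjacent modules then have standardized-profile
#' correlation about `cos(2*pi/M)`, i.e. clearly below typical edge
#' thresholds for M = 9. For a single domain the matrix is all ones
#' (homogeneous tissue).
#'
#' @param n_modules,n_domains dimensions.
#' @param contrast minimum fold-change between a module's most and least
#'   active domains.
#' @return `n_modules` x `n_domains` matrix.
#' @export
default_module_activity <- function(n_modules, n_domains, contrast = 4) {
  if (n_domains <= 1L) return(matrix(1, n_modules, n_domains))
  theta <- 2 * pi * (seq_len(n_modules) - 1L) / n_modules
  phi <- 2 * pi * (seq_len(n_domains) - 1L) / n_domains
  v <- outer(theta, phi, function(t, p) cos(t - p))
  # min over modules of (max - min) cosine spread is 1.5 for >= 3 domains
  spread <- min(apply(v, 1, function(r) max(r) - min(r)))
  a <- log(contrast) / spread
  exp(a * v)
}

#' The default study conditions: nine modules, three domains, one planted
#' dual-pathway regulator
#'
#' A 50 x 30 lattice (1500 spots) in three band domains; 900 genes in nine
#' modules with activity contrast >= 4x; nine TF genes, one per module and
#' family, with a TCP-family TF planted as coregulator of two pathway
#' sets: it targets two `catechin_synthesis` and two `theanine_hydrolysis`
#' genes in its own module, while a bHLH TF and a MYB TF each regulate two
#' genes of a single set in other modules. Each pathway set also carries
#' two unregulated genes in the TCP module, so promoter evidence is needed
#' to separate true targets from merely coexpressed genes.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [tissue_spec()].
#' @return a `tissue_spec`.
#' @export
default_tissue_spec <- function(seed = 1L, ...) {
  n_genes <- 900L; n_tfs <- 9L; K <- 9L
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  tf_ids <- gene_ids[(n_genes - n_tfs + 1L):n_genes]
  families <- c("bHLH", "MYB", "WRKY", "ERF", "TCP", "bZIP", "C2H2", "GRAS",
                "NAC")
  tf_modules <- 0:8                      # TF i sits in module i-1; TCP -> 4
  module_of <- function(i) (i - 1L) %% K # layout used by simulate_tissue
  in_module <- function(m) gene_ids[which(module_of(seq_len(n_genes - n_tfs)) == m)]
  tcp <- tf_ids[5]; bhlh <- tf_ids[1]; myb <- tf_ids[2]
  mod4 <- in_module(4L)
  tcp_targets <- mod4[1:4]               # 2 catechin + 2 theanine targets
  mod4_decoys <- mod4[5:8]               # coexpressed but unregulated
  bhlh_targets <- in_module(0L)[1:2]
  myb_targets <- in_module(1L)[1:2]
  tissue_spec(
    seed = seed, n_genes = n_genes, n_modules = K, n_tfs = n_tfs,
    tf_module_map = tf_modules, tf_families = families,
    target_map = stats::setNames(
      list(tcp_targets, bhlh_targets, myb_targets),
      c(tcp, bhlh, myb)),
    pathway_map = list(
      catechin_synthesis = c(tcp_targets[1:2], bhlh_targets, mod4_decoys[1:2]),
      theanine_hydrolysis = c(tcp_targets[3:4], myb_targets, mod4_decoys[3:4])),
    ...)
}

#' Simulate a spatial count matrix with planted domains and modules
#'
#' Draws the negative-binomial counts described in [tissue_spec()] and
#' returns the count matrix, spot geometry, gene annotation (TF flags,
#' families, pathway tags, one `module_<m>` enrichment term per gene) and
#' the ground truth needed for parameter-recovery checks.
#'
#' @param spec a [tissue_spec()].
#' @param seed seed override; defaults to `spec$seed`.
#' @return list with `matrix` ([count_matrix()]), `geometry`,
#'   `annotation`, `truth`. `truth` carries `domain_of` (named, 0-based),
#'   `module_of` (named, 0-based), `true_edges` (data.frame `tf_gene`,
#'   `target_gene`, `sign`), and `metabolite_loadings`.
#' @export
simulate_tissue <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(derive_seed(seed, 11L), {
    n_spots <- spec$grid_width * spec$grid_height
    barcodes <- sprintf("S%05d", seq_len(n_spots))
    xy <- expand.grid(x = seq_len(spec$grid_width) - 1L,
                      y = seq_len(spec$grid_height) - 1L)
    geometry <- data.frame(barcode = barcodes, x = xy$x, y = xy$y,
                           in_tissue = TRUE, stringsAsFactors = FALSE)
    domain_of <- switch(spec$domain_layout,
      bands = pmin(spec$n_domains - 1L,
                   floor(xy$x / (spec$grid_width / spec$n_domains))),
      voronoi = {
        cx <- stats::runif(spec$n_domains, 0, spec$grid_width - 1L)
        cy <- stats::runif(spec$n_domains, 0, spec$grid_height - 1L)
        d2 <- outer(xy$x, cx, "-")^2 + outer(xy$y, cy, "-")^2
        max.col(-d2) - 1L
      })
    domain_of <- stats::setNames(as.integer(domain_of), barcodes)

    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
    n_struct <- spec$n_genes - spec$n_tfs
    module_of <- integer(spec$n_genes)
    module_of[seq_len(n_struct)] <- (seq_len(n_struct) - 1L) %% spec$n_modules
    if (spec$n_tfs > 0L) {
      module_of[(n_struct + 1L):spec$n_genes] <- spec$tf_module_map
    }
    module_of <- stats::setNames(module_of, gene_ids)

    base_mean <- spec$base_mean
    if (is.null(base_mean)) {
      base_mean <- stats::rlnorm(spec$n_genes, meanlog = log(2), sdlog = 1)
    } else {
      base_mean <- rep_len(base_mean, spec$n_genes)
    }
    lib <- stats::rlnorm(n_spots, 0, spec$libsize_sigma)

    mu <- (lib %o% base_mean) *
      spec$module_activity[cbind(rep(module_of + 1L, each = n_spots),
                                 rep(domain_of + 1L, times = spec$n_genes))]
    counts <- matrix(stats::rnbinom(length(mu), size = spec$nb_dispersion,
                                    mu = mu),
                     nrow = n_spots, ncol = spec$n_genes)
    cm <- count_matrix(counts, barcodes, gene_ids)

    is_tf <- c(rep(FALSE, n_struct), rep(TRUE, spec$n_tfs))
    tf_family <- character(spec$n_genes)
    if (spec$n_tfs > 0L) tf_family[is_tf] <- spec$tf_families
    pathway_tags <- rep("", spec$n_genes)
    for (tag in names(spec$pathway_map)) {
      idx <- match(spec$pathway_map[[tag]], gene_ids)
      if (anyNA(idx)) stopf("pathway '%s' names unknown genes", tag)
      pathway_tags[idx] <- ifelse(pathway_tags[idx] == "", tag,
                                  paste(pathway_tags[idx], tag, sep = ";"))
    }
    annotation <- validate_gene_annotation(data.frame(
      gene_id = gene_ids,
      symbol = ifelse(is_tf, paste0("TF_", tf_family), gene_ids),
      is_tf = is_tf, tf_family = tf_family, pathway_tags = pathway_tags,
      term_ids = paste0("module_", module_of), stringsAsFactors = FALSE))

    true_edges <- data.frame(tf_gene = character(0), target_gene = character(0),
                             sign = integer(0), stringsAsFactors = FALSE)
    for (tf in names(spec$target_map)) {
      tg <- spec$target_map[[tf]]
      if (!all(tg %in% gene_ids) || !(tf %in% gene_ids)) {
        stopf("target_map names unknown genes for TF '%s'", tf)
      }
      if (length(tg)) {
        true_edges <- rbind(true_edges,
                            data.frame(tf_gene = tf, target_gene = tg,
                                       sign = 1L, stringsAsFactors = FALSE))
      }
    }
    metabolite_loadings <- list()
    if ("catechin_synthesis" %in% names(spec$pathway_map)) {
      g <- spec$pathway_map$catechin_synthesis
      metabolite_loadings$catechin <- list(genes = g,
                                           weights = rep(1, length(g)),
                                           sign = 1L)
    }
    if ("theanine_hydrolysis" %in% names(spec$pathway_map)) {
      g <- spec$pathway_map$theanine_hydrolysis
      metabolite_loadings$theanine <- list(genes = g,
                                           weights = rep(1, length(g)),
                                           sign = -1L)
    }
    truth <- list(domain_of = domain_of, module_of = module_of,
                  true_edges = true_edges,
                  metabolite_loadings = metabolite_loadings,
                  base_mean = stats::setNames(base_mean, gene_ids))
    list(matrix = cm, geometry = geometry, annotation = annotation,
         truth = truth)
  })
}

#' Simulate promoters and a family motif library with planted sites
#'
#' Backgrounds are uniform over A/C/G/T. Each TF family named in the truth
#' gets a random-consensus PWM (consensus base probability 0.91); for
#' every true edge one exact consensus instance of the TF's family motif
#' is planted at a uniform random offset and strand in the target
#' promoter, avoiding previously planted sites. Non-target promoters get
#' no deliberate planting, so any hits there are the chance hits the dual
#' criterion must reject. The planted-site invariant (every target
#' promoter contains its family consensus as a forward or
#' reverse-complement substring) is re-checked before returning.
#'
#' @param truth ground truth from [simulate_tissue()].
#' @param spec the same [tissue_spec()].
#' @param seed seed override; defaults to `spec$seed`.
#' @param annotation annotation from the same simulation (supplies the
#'   family of each TF).
#' @return list with `promoters` (named character), `library` (named PWM
#'   list), `planted_sites` (data.frame `gene_id`, `family`, `position`,
#'   `strand`).
#' @export
simulate_promoters <- function(truth, spec, annotation, seed = spec$seed) {
  if (spec$promoter_len < spec$motif_width) {
    stopf("promoter_len shorter than motif_width")
  }
  with_seed(derive_seed(seed, 23L), {
    genes <- names(truth$module_of)
    L <- spec$promoter_len
    w <- spec$motif_width
    promoters <- vapply(genes, function(g) {
      paste(sample(BASES, L, replace = TRUE), collapse = "")
    }, character(1))

    fam_of <- stats::setNames(annotation$tf_family, annotation$gene_id)
    fams <- unique(annotation$tf_family[annotation$is_tf])
    library <- list()
    for (fam in fams) {
      consensus <- sample(BASES, w, replace = TRUE)
      probs <- matrix(0.03, 4, w, dimnames = list(BASES, NULL))
      probs[cbind(match(consensus, BASES), seq_len(w))] <- 0.91
      library[[fam]] <- new_pwm(fam, probs)
    }

    planted <- data.frame(gene_id = character(0), family = character(0),
                          position = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
    occupied <- list()
    if (nrow(truth$true_edges)) {
      for (i in seq_len(nrow(truth$true_edges))) {
        tf <- truth$true_edges$tf_gene[i]
        tg <- truth$true_edges$target_gene[i]
        fam <- fam_of[[tf]]
        cons <- pwm_consensus(library[[fam]])
        strand <- sample(c("+", "-"), 1L)
        site <- if (strand == "+") cons else reverse_complement(cons)
        taken <- occupied[[tg]]
        for (try in 1:100) {
          pos <- sample.int(L - w + 1L, 1L) - 1L   # 0-based offset
          clash <- any(vapply(taken, function(iv) pos < iv[2] && iv[1] < pos + w,
                              logical(1)))
          if (!clash) break
        }
        substr(promoters[[tg]], pos + 1L, pos + w) <- site
        occupied[[tg]] <- c(taken, list(c(pos, pos + w)))
        planted <- rbind(planted, data.frame(
          gene_id = tg, family = fam, position = pos, strand = strand,
          stringsAsFactors = FALSE))
      }
      # re-check the planted-site invariant post hoc
      for (i in seq_len(nrow(truth$true_edges))) {
        tg <- truth$true_edges$target_gene[i]
        fam <- fam_of[[truth$true_edges$tf_gene[i]]]
        cons <- pwm_consensus(library[[fam]])
        if (!grepl(cons, promoters[[tg]], fixed = TRUE) &&
            !grepl(reverse_complement(cons), promoters[[tg]], fixed = TRUE)) {
          stopf("planted site lost in promoter of '%s'", tg)
        }
      }
    }
    list(promoters = promoters, library = library, planted_sites = planted)
  })
}

#' Simulate a paired control/knockdown expression-and-metabolite assay
#'
#' Emulates a transient antisense-oligonucleotide knockdown of one TF:
#' control replicates draw the TF at its baseline mean, knockdown
#' replicates at `delta` times that mean; each of the TF's targets is
#' shifted by `sign * beta * (TF deviation from baseline)`; each
#' metabolite is `sign * sum(weights * pathway gene expression)` plus
#' noise, so a positively loaded metabolite falls and a negatively loaded
#' one rises when the TF is silenced.
#'
#' @param truth ground truth from [simulate_tissue()].
#' @param spec the same [tissue_spec()].
#' @param n_reps replicates per condition (>= 2).
#' @param delta knockdown fraction of baseline TF expression, in (0, 1).
#' @param beta target response per unit TF deviation.
#' @param noise_sd replicate noise sd (expression and metabolite).
#' @param seed integer seed.
#' @param tf_gene TF to silence; default the TF with the most true
#'   targets.
#' @param baseline baseline mean expression of TF and targets.
#' @return data.frame: one row per replicate, columns `condition`
#'   (`"control"`/`"knockdown"`), `replicate`, one column per involved
#'   gene, one per metabolite.
#' @export
simulate_knockdown <- function(truth, spec, n_reps = 6L, delta = 0.2,
                               beta = 1, noise_sd = 0.5, seed = spec$seed,
                               tf_gene = NULL, baseline = 10) {
  if (n_reps < 2L) stopf("n_reps must be >= 2")
  if (delta <= 0 || delta >= 1) stopf("delta must lie strictly in (0, 1)")
  edges <- truth$true_edges
  if (is.null(tf_gene)) {
    if (!nrow(edges)) stopf("no true edges: name tf_gene explicitly")
    tf_gene <- names(sort(table(edges$tf_gene), decreasing = TRUE))[1]
  }
  tg <- edges[edges$tf_gene == tf_gene, , drop = FALSE]
  loadings <- truth$metabolite_loadings
  other <- setdiff(unique(unlist(lapply(loadings, `[[`, "genes"))),
                   c(tf_gene, tg$target_gene))
  with_seed(derive_seed(seed, 37L), {
    cond <- rep(c("control", "knockdown"), each = n_reps)
    n <- length(cond)
    tf_mu <- ifelse(cond == "control", baseline, baseline * delta)
    tf_x <- stats::rnorm(n, tf_mu, noise_sd)
    expr <- list()
    expr[[tf_gene]] <- tf_x
    for (i in seq_len(nrow(tg))) {
      expr[[tg$target_gene[i]]] <-
        baseline + tg$sign[i] * beta * (tf_x - baseline) +
        stats::rnorm(n, 0, noise_sd)
    }
    for (g in other) expr[[g]] <- stats::rnorm(n, baseline, noise_sd)
    met <- list()
    for (m in names(loadings)) {
      ld <- loadings[[m]]
      tot <- 0
      for (j in seq_along(ld$genes)) {
        g <- ld$genes[j]
        gx <- if (g %in% names(expr)) expr[[g]] else rep(baseline, n)
        tot <- tot + ld$weights[j] * gx
      }
      met[[m]] <- ld$sign * tot + stats::rnorm(n, 0, noise_sd)
    }
    out <- data.frame(condition = cond, replicate = rep(seq_len(n_reps), 2),
                      stringsAsFactors = FALSE)
    for (g in names(expr)) out[[g]] <- expr[[g]]
    for (m in names(met)) out[[m]] <- met[[m]]
    out
  })
}

#' Analytic standardized cluster profile of a tissue spec
#'
#' The infinite-sampling limit of the standardized pseudo-bulk profile:
#' for a gene in module m the per-domain log expression is
#' `log(module_activity[m, d])` up to a gene constant, which
#' standardization removes. Used to exercise the network stage free of
#' expression noise.
#'
#' @param spec a [tissue_spec()].
#' @return list mimicking a standardized cluster profile: `values`
#'   (genes x domains), `gene_ids`, `cluster_ids`.
#' @export
expected_zprofile <- function(spec) {
  sim_genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_struct <- spec$n_genes - spec$n_tfs
  module_of <- c((seq_len(n_struct) - 1L) %% spec$n_modules,
                 if (spec$n_tfs > 0L) spec$tf_module_map)
  vals <- log(spec$module_activity[module_of + 1L, , drop = FALSE])
  rownames(vals) <- sim_genes
  cluster_profile(vals, sim_genes, paste0("D", seq_len(spec$n_domains) - 1L)) |>
    standardize_profile()
}
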