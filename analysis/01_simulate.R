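#!/usr/bin/env Rscript

# Stage 1 — generate the study data set.
#
# Simulates the default synthetic tissue section: a 50 x 30 Visium-style
# spot lattice in three band-shaped tissue domains, 900 genes in nine
# coexpression modules (activity contrast >= 4x between a module's most
# and least active domains), nine TF genes (one per module and family),
# and one TCP-family TF planted as a dual-pathway regulator with two
# catechin-synthesis and two theanine-hydrolysis targets. Promoters carry
# exact consensus binding sites for every true TF-target edge.
#
# Writes the standard input file set (MTX triplet, positions CSV,
# annotation TSV, promoter FASTA, MEME motifs) plus the ground truth to
# results/data/.

suppressMessages(library(spotnet))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- default_tissue_spec(seed = seed)
sim <- simulate_tissue(spec)
prom <- simulate_promoters(sim$truth, spec, sim$annotation)

write_count_matrix(sim$matrix, file.path(out, "counts"))
write_spot_positions(sim$geometry, file.path(out, "positions.csv"))
write_gene_annotation(sim$annotation, file.path(out, "genes.tsv"))
write_promoters(prom$promoters, file.path(out, "promoters.fa"))
write_motifs(prom$library, file.path(out, "motifs.meme"))
jsonlite::write_json(
  list(seed = seed,
       domain_of = as.list(sim$truth$domain_of),
       module_of = as.list(sim$truth$module_of),
       true_edges = sim$truth$true_edges,
       planted_sites = prom$planted_sites),
  file.path(out, "truth.json"), auto_unbox = TRUE)

cat(sprintf("simulated %d spots x %d genes (%d nonzero counts)\n",
            nrow(sim$matrix$counts), ncol(sim$matrix$counts),
            length(sim$matrix$counts@x)))
cat(sprintf("planted %d true TF-target edges across %d pathway sets\n",
            nrow(sim$truth$true_edges), length(spec$pathway_map)))
cat("inputs written to", out, "\n")
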