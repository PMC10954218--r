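#!/usr/bin/env Rscript

# Stage 6 - diffusion-flood pseudotime and the genotype comparison.
#
# Builds the diffusion transition matrix on the joint embedding, floods
# from root cells (highest progenitor-marker expression), and compares
# the wild-type and mutant pseudotime distributions with a two-sample
# Kolmogorov-Smirnov test.

suppressMessages(library(gastrufate))

cm <- read_mtx_layers("results/filtered")
lg <- normalize_log(cm)
pe <- normalize_pearson(cm)
meta <- cm$cell_meta
sel <- select_pcs(pe, genes = variable_genes(lg, 2000))

T_ <- diffusion_transitions(sel$scores, k_neighbors = 15)
gm <- cm$gene_meta
roots <- root_cells_by_markers(lg, gm$gene[gm$marker_pop %in% "NMP"],
                               n_roots = 20)
pt <- flood_pseudotime(T_, roots, n_floods = 100, seed = 401)

rho <- cor(pt$pseudotime, meta$latent_time, method = "spearman")
cat("Spearman(pseudotime, latent time) =", round(rho, 3), "\n")

ks <- compare_pseudotime(pt$pseudotime[meta$genotype == "wt"],
                         pt$pseudotime[meta$genotype == "mut"],
                         meta$population[meta$genotype == "wt"],
                         meta$population[meta$genotype == "mut"])
cat("KS comparison of genotype pseudotime distributions:\n")
print(ks)

utils::write.table(
  data.frame(barcode = meta$barcode, pseudotime = round(pt$pseudotime, 5),
             mean_iteration = round(pt$mean_iteration, 3)),
  "results/pseudotime.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ks, "results/pseudotime_ks.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
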