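#!/usr/bin/env Rscript

# Stage 4 - project mutant cells onto the wild-type populations, run the
# reverse-projection control, and test composition differences.

suppressMessages(library(gastrufate))

cm <- read_mtx_layers("results/filtered")
lg <- normalize_log(cm)
meta <- cm$cell_meta
wt <- meta$genotype == "wt"; mut <- !wt
vg <- variable_genes(lg, 2000)
wt_clusters <- utils::read.table("results/wt_clusters.tsv", header = TRUE,
                                 sep = "\t")$cluster

fa <- find_anchors(lg[, wt], lg[, mut], genes = vg)
fwd <- transfer_labels(fa, wt_clusters)
cat("forward projection:", nrow(fa$pairs), "anchors;",
    sum(fwd$imputed), "query cells imputed from neighbors\n")

# reverse: cluster the mutant independently, project wild-type onto it
sel_m <- select_pcs(normalize_pearson(cm)[, mut, drop = FALSE], genes = vg)
cons_m <- consensus_cluster_number(sel_m, k_neighbors = 15, k_max = 8,
                                   seed = 308)
ra <- find_anchors(lg[, mut], lg[, wt], genes = vg)
rev_ <- transfer_labels(ra, cons_m$labels)
chk <- reverse_projection_check(wt_clusters, fwd$label,
                                cons_m$labels, rev_$label)
cat("forward vs reverse composition deltas:\n")
print(chk$table)
cat("sign agreement:", round(chk$sign_agreement, 3),
    " delta correlation:", round(chk$delta_correlation, 3), "\n")

labels_all <- character(nrow(meta))
labels_all[wt] <- as.character(wt_clusters)
labels_all[mut] <- as.character(fwd$label)
comp <- composition_test(labels_all, meta$sample, meta$genotype)
cat("composition tests (per population, Welch t):\n")
print(comp$tests)

utils::write.table(fwd, "results/mut_projected_labels.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(comp$proportions, "results/composition.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(comp$tests, "results/composition_tests.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(chk$table, "results/reverse_projection.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
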