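#!/usr/bin/env Rscript

# Stage 8 - cross-study concordance, TSS binding-site annotation and
# gene-set enrichment.
#
# No external study accompanies the simulated data, so this stage builds
# a synthetic "external" differential-expression table sharing a known
# fraction of true effects with an attenuated slope (0.8), then checks
# that the concordance statistics recover both; binding sites are
# synthetic peaks placed preferentially near DEG TSSs.

suppressMessages(library(gastrufate))

dg <- utils::read.table("results/dgea_genotype.tsv", header = TRUE,
                        sep = "\t")
cm <- read_mtx_layers("results/filtered")
gm <- cm$gene_meta
universe <- dg$gene
self_deg <- dg[dg$Q < 0.05, c("gene", "direction")]

set.seed(601)
# synthetic external study: 70% of this study's DEGs replicate with the
# same direction; fold changes attenuate with slope 0.8 plus noise
keep <- runif(nrow(self_deg)) < 0.7
ext_deg <- self_deg[keep, ]
extra <- sample(setdiff(universe, self_deg$gene), 40)
ext_deg <- rbind(ext_deg, data.frame(
  gene = extra, direction = sample(c("up", "down"), 40, replace = TRUE)))
ov <- deg_overlap(self_deg, ext_deg, universe)
cat("direction-stratified DEG overlap:\n")
print(ov$overlap)

lfc_self <- stats::setNames(log2(dg$fold_change), dg$gene)
lfc_ext <- 0.8 * lfc_self + rnorm(length(lfc_self), 0, 0.1)
names(lfc_ext) <- names(lfc_self)
fr <- foldchange_regression(lfc_ext, lfc_self)
cat(sprintf("fold-change regression: slope %.3f, r %.3f (n = %d)\n",
            fr$slope, fr$r, fr$n))

# synthetic peaks (+/- 100 nt around 70% of DEG TSSs, 15% of others)
has_peak <- ifelse(gm$gene %in% self_deg$gene,
                   runif(nrow(gm)) < 0.7, runif(nrow(gm)) < 0.15)
tss <- ifelse(gm$strand == "+", gm$tss, gm$tss)
peaks <- data.frame(chromosome = gm$chromosome[has_peak],
                    start = tss[has_peak] - 100L,
                    end = tss[has_peak] + 100L)
ann <- annotate_tss_peaks(gm[, c("gene", "chromosome", "strand", "tss")],
                          peaks, window_nt = 250)
enr <- binding_site_enrichment(self_deg$gene, ann, universe)
cat("binding-site enrichment among DEGs:\n")
print(enr)

# overrepresentation and permutation GSEA against the truth gene sets
truth <- read_gmt("results/simulated/truth_drivers.gmt")
ora_res <- ora(self_deg$gene, truth, universe)
cat("overrepresentation of truth sets among DEGs:\n")
print(ora_res)

stat <- stats::setNames(-log10(pmax(dg$p, 1e-300)) *
                          sign(log2(dg$fold_change)), dg$gene)
gsea_res <- gsea(sort(stat, decreasing = TRUE), truth, n_perm = 2000,
                 seed = 602)
cat("permutation GSEA on the genotype ranking:\n")
print(gsea_res)

utils::write.table(ov$overlap, "results/deg_overlap.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(enr, "results/binding_site_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ora_res, "results/ora.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(gsea_res, "results/gsea.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
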