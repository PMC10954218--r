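test_that("per-cell QC metrics match hand computation and degenerate cases", {
  # genes x cells; gene 3 is mitochondrial. Cell 1 is the worked 3-gene
  # toy (2, 0, 5): pct_mito = 5/7, two detected genes.
  counts <- cbind(toy = c(2, 0, 5),
                  empty = c(0, 0, 0),
                  allmito = c(0, 0, 4))
  rownames(counts) <- c("g1", "g2", "mt1")
  cm <- count_matrix(counts,
                     gene_meta = data.frame(gene = rownames(counts),
                                            mito = c(FALSE, FALSE, TRUE)))
  qc <- compute_cell_qc(cm)
  expect_equal(qc$n_counts, c(7, 0, 4))
  expect_equal(qc$n_genes, c(2, 0, 1))
  expect_equal(qc$pct_mito, c(5 / 7, 0, 1))
  # all-zero cell: pct_mito defined as 0
  cm0 <- count_matrix(matrix(0, 2, 1, dimnames = list(c("a", "mt"), "c")),
                      gene_meta = data.frame(gene = c("a", "mt"),
                                             mito = c(FALSE, TRUE)))
  expect_equal(compute_cell_qc(cm0)$pct_mito, 0)
  cm_nomito <- count_matrix(counts,
                            gene_meta = data.frame(gene = rownames(counts)))
  expect_error(compute_cell_qc(cm_nomito), "mito")
})

test_that("MAD filter removes nothing from identical cells and applies the zero-MAD fallback", {
  same <- data.frame(barcode = paste0("c", 1:12),
                     n_counts = 100, n_genes = 50, pct_mito = 0.05)
  out <- suppressWarnings(mad_filter(same))
  expect_true(all(out$keep))
  # {10,10,10,10,100}: median 10, MAD 0, IQR 0 -> any value != median falls
  toy <- data.frame(barcode = paste0("c", 1:10),
                    n_counts = c(rep(10, 8), 100, 100),
                    n_genes = 50, pct_mito = 0.05)
  out2 <- suppressWarnings(mad_filter(toy))
  expect_equal(which(!out2$keep), c(9, 10))
})

test_that("MAD filtering is per stage group, sided as configured, and idempotent on clean data", {
  set.seed(5)
  n <- 300
  met <- data.frame(
    barcode = paste0("c", 1:n),
    n_counts = rnorm(n, 2000, 100),
    n_genes = rnorm(n, 800, 40),
    pct_mito = runif(n, 0.01, 0.05),
    stage = rep(c("LB", "CC"), each = n / 2))
  # plant outliers in one stage only
  met$pct_mito[1:5] <- 0.6        # high mito: removed (upper-sided)
  met$n_counts[6:10] <- 8000      # doublet-like: removed (two-sided)
  met$pct_mito[11:15] <- 0.0001   # LOW mito: kept (upper-sided only)
  out <- mad_filter(met)
  expect_true(all(!out$keep[1:10]))
  expect_true(all(out$keep[11:15]))
  # idempotence with frozen bounds: every kept cell is inside the
  # recorded per-group thresholds, so re-applying them removes nothing
  kept <- met[out$keep, ]
  for (grp in unique(kept$stage)) {
    for (mc in c("n_counts", "n_genes")) {
      b <- out$bounds[[paste(grp, mc)]]
      x <- kept[[mc]][kept$stage == grp]
      expect_true(all(x >= b["lower"] & x <= b["upper"]))
    }
    b <- out$bounds[[paste(grp, "pct_mito")]]
    expect_true(all(kept$pct_mito[kept$stage == grp] <= b["upper"]))
  }
})

test_that("MAD filter recovers injected artifacts on simulated data", {
  # one homogeneous population: depth is then the only systematic
  # source of count variation, the regime the doublet criterion assumes
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 500,
                    n_genes = 180, n_program = 10, n_decoys = 10,
                    populations = data.frame(name = "W", branch = "pre",
                                             t0 = 0, t1 = 1),
                    branch_time = 1,
                    libsize_lognorm_params = c(0, 0.15),
                    sample_depth_sdlog = 0.05,
                    outlier_fraction = 0.03, doublet_fraction = 0.02,
                    seed = 21)
  sim <- inject_qc_artifacts(simulate_branching_lineage(cfg), cfg)
  qc <- compute_cell_qc(sim$cm)
  out <- mad_filter(qc)
  art <- sim$cm$cell_meta$artifact
  expect_gte(mean(!out$keep[art != "none"]), 0.9)
  expect_lte(mean(!out$keep[art == "none"]), 0.02)
})

test_that("depth subsampling equalizes expected totals, conserves zeros, and is seeded", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_branching_lineage(cfg)
  cm <- sim$cm
  tot0 <- tapply(Matrix::colSums(cm$counts), cm$cell_meta$sample, sum)
  thin <- subsample_depth(cm, seed = 9)
  tot1 <- tapply(Matrix::colSums(thin$counts), thin$cell_meta$sample, sum)
  expect_true(all(tot1 <= tot0 + 1e-9))
  sds <- sqrt(min(tot0))
  expect_true(all(abs(tot1 - min(tot0)) < 4 * sds))
  # zeros conserved, counts never increase
  expect_true(all(thin$counts@x >= 0))
  d <- cm$counts - thin$counts
  expect_true(all(d@x >= 0))
  # determinism
  thin2 <- subsample_depth(cm, seed = 9)
  expect_identical(as.matrix(thin$counts), as.matrix(thin2$counts))
  # already-equal samples are untouched
  eq <- cm
  expect_identical(
    as.matrix(subsample_depth(eq, seed = 1,
                              stage_group = eq$cell_meta$sample)$counts),
    as.matrix(eq$counts))
})

test_that("Pearson residuals are centered, unit-variance for Poisson genes, and clipped", {
  set.seed(41)
  n <- 1500
  depth <- rep(1, n)
  X <- rbind(
    t(sapply(1:40, function(i) rpois(n, 8))),     # Poisson genes
    matrix(0, 3, n),                              # zero genes
    t(sapply(1:40, function(i) rpois(n, 2))))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  colnames(X) <- paste0("c", seq_len(n))
  res <- normalize_pearson(X)
  expect_true(all(is.finite(res)))
  expect_true(all(abs(res) <= sqrt(n) + 1e-9))
  expect_true(all(res[41:43, ] == 0))
  expect_setequal(attr(res, "zero_genes"), paste0("g", 41:43))
  v <- apply(res[1:40, ], 1, var)
  expect_lt(abs(mean(v) - 1), 0.1)
})

test_that("residual rank profile is invariant to a proportional depth change", {
  set.seed(43)
  base <- matrix(rpois(60 * 100, 6), 60, 100,
                 dimnames = list(paste0("g", 1:60), paste0("c", 1:100)))
  doubled <- base
  doubled[, 1] <- base[, 1] * 2     # same composition, double depth
  r1 <- normalize_pearson(base)
  r2 <- normalize_pearson(doubled)
  expect_gt(cor(rank(r1[, 1]), rank(r2[, 1]), method = "spearman"), 0.99)
})

test_that("cell-cycle scoring assigns phases from marker programs", {
  set.seed(51)
  n_per <- 80
  genes <- c(paste0("s", 1:10), paste0("m", 1:10), paste0("bg", 1:60))
  phase_truth <- rep(c("G1", "S", "G2M"), each = n_per)
  mk <- function(ph) {
    s_mu <- ifelse(ph == "S", 12, 2)
    m_mu <- ifelse(ph == "G2M", 12, 2)
    c(rpois(10, s_mu), rpois(10, m_mu), rpois(60, 4))
  }
  X <- sapply(phase_truth, mk)
  rownames(X) <- genes; colnames(X) <- paste0("c", seq_along(phase_truth))
  lg <- normalize_log(X)
  out <- assign_cell_cycle(lg, paste0("s", 1:10), paste0("m", 1:10), seed = 2)
  expect_gte(mean(out$phase == phase_truth), 0.85)
  expect_error(assign_cell_cycle(lg, c("s1", "m1"), paste0("m", 1:10)),
               "overlap")
  # a cell expressing nothing scores nonpositive and lands in G1
  X0 <- cbind(X, zero = rep(0, nrow(X)))
  out0 <- assign_cell_cycle(normalize_log(X0), paste0("s", 1:10),
                            paste0("m", 1:10), seed = 2)
  expect_equal(out0$phase[ncol(X0)], "G1")
})
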