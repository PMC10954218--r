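test_that("kinetics reach the closed-form steady state under constant transcription", {
  tr <- kinetics_trajectory(rep(4, 200), beta = 2, gamma = 0.8)
  # fixed point: u = alpha/beta, s = alpha/gamma, u/s = gamma/beta
  expect_equal(tr$u[1, 200], 4 / 2, tolerance = 1e-10)
  expect_equal(tr$s[1, 200], 4 / 0.8, tolerance = 1e-10)
  expect_equal(tr$u[1, 200] / tr$s[1, 200], 0.8 / 2, tolerance = 1e-10)
  # and stay there for the whole trajectory
  expect_true(all(abs(tr$u[1, ] - 2) < 1e-10))
})

test_that("a symmetric branch point sends about half of post-branch cells to each fate", {
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 5000,
                    n_genes = 180, n_program = 10, n_decoys = 10,
                    branch_prob_wt = 0.5, branch_prob_mut = 0.5, seed = 2)
  sim <- simulate_branching_lineage(cfg)
  post <- sim$cm$cell_meta$branch != "pre"
  n <- sum(post)
  frac_a <- mean(sim$cm$cell_meta$branch[post] == "A")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the seed fully determines the simulated output", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_branching_lineage(cfg)
  b <- simulate_branching_lineage(cfg)
  expect_identical(as.matrix(a$cm$counts), as.matrix(b$cm$counts))
  expect_identical(a$cm$cell_meta, b$cm$cell_meta)
  expect_identical(a$truth$fate_prob, b$truth$fate_prob)
  c_ <- simulate_branching_lineage(small_sim_config(seed = 8))
  expect_false(identical(as.matrix(a$cm$counts), as.matrix(c_$cm$counts)))
})

test_that("Monte-Carlo count means match the integrator expectations in the Poisson limit", {
  cfg <- sim_config(n_samples_per_genotype = 1, n_cells_per_sample = 5,
                    n_genes = 180, n_program = 10, n_decoys = 10,
                    nb_dispersion = Inf, seed = 4)
  sim <- simulate_branching_lineage(cfg, keep_expectation = TRUE)
  keep <- sim$expected_spliced > 2   # relative tolerance needs signal
  acc <- matrix(0, nrow(sim$expected_spliced), ncol(sim$expected_spliced))
  n_rep <- 3000
  for (r in seq_len(n_rep)) acc <- acc + resample_counts(sim, seed = r)$spliced
  rel_err <- abs(acc[keep] / n_rep - sim$expected_spliced[keep]) /
    sim$expected_spliced[keep]
  # MC error: sd/mean/sqrt(n_rep) ~ 0.6% at mu > 2; check the bulk and cap
  expect_lt(mean(rel_err), 0.01)
  expect_lt(max(rel_err), 0.05)
})

test_that("fate probabilities are valid and generative bias is recoverable from truth", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_branching_lineage(cfg)
  fp <- sim$truth$fate_prob
  expect_true(all(abs(rowSums(fp) - 1) < 1e-12))
  expect_true(all(fp >= 0 & fp <= 1))
  meta <- sim$cm$cell_meta
  pre_wt <- meta$branch == "pre" & meta$genotype == "wt"
  expect_true(all(fp[pre_wt, "A"] == cfg$branch_prob_wt))
  post <- meta$branch != "pre"
  expect_true(all(fp[post, "A"] %in% c(0, 1)))
  # empirical fate fractions track the branch probabilities
  for (gt in c("wt", "mut")) {
    sel <- meta$genotype == gt & post
    p <- if (gt == "wt") cfg$branch_prob_wt else cfg$branch_prob_mut
    expect_lt(abs(mean(meta$branch[sel] == "A") - p),
              4 * sqrt(p * (1 - p) / sum(sel)))
  }
})

test_that("the persistent regulator decays along time in wt but persists in the mutant", {
  cfg <- sim_config(n_samples_per_genotype = 3, n_cells_per_sample = 400,
                    n_genes = 180, n_program = 10, n_decoys = 10, seed = 6)
  sim <- simulate_branching_lineage(cfg)
  reg <- sim$cm$gene_meta$gene[sim$cm$gene_meta$role == "regulator"]
  lg <- normalize_log(sim$cm)
  meta <- sim$cm$cell_meta
  bins <- cut(meta$latent_time, seq(0, 1, 0.25), include.lowest = TRUE)
  mwt <- tapply(lg[reg, meta$genotype == "wt"],
                bins[meta$genotype == "wt"], mean)
  mmut <- tapply(lg[reg, meta$genotype == "mut"],
                 bins[meta$genotype == "mut"], mean)
  # monotone non-increasing in wt (small tolerance for sampling noise)
  expect_true(all(diff(mwt) < 0.05))
  expect_gt(mwt[1], mwt[4] + 0.4)
  # mutant profile bounded below by the wt profile, clearly so at late times
  expect_true(all(mmut >= mwt - 0.05))
  expect_gt(mmut[4], mwt[4] + 0.4)
})

test_that("artifact injection is exact, flagged, and an identity at rate zero", {
  cfg0 <- small_sim_config(seed = 11)
  sim0 <- simulate_branching_lineage(cfg0)
  expect_identical(inject_qc_artifacts(sim0, cfg0), sim0)

  cfg <- small_sim_config(seed = 11, outlier_fraction = 0.03,
                          doublet_fraction = 0.02)
  sim <- inject_qc_artifacts(simulate_branching_lineage(cfg), cfg)
  n0 <- ncol(sim0$cm$counts)
  flags <- sim$cm$cell_meta$artifact
  expect_equal(sum(flags == "outlier"), round(0.03 * n0))
  expect_equal(sum(flags == "doublet"), round(0.02 * n0))
  expect_equal(ncol(sim$cm$counts), n0 + round(0.05 * n0))
  expect_true(all(abs(rowSums(sim$truth$fate_prob) - 1) < 1e-12))

  # doublet construction: total counts are exactly the sum of two cells
  dbl <- which(flags == "doublet")[1]
  bc <- sim$cm$cell_meta$barcode[dbl]
  src1 <- sub("^dbl[0-9]+_", "", bc)
  tot <- Matrix::colSums(sim$cm$counts)
  expect_gte(tot[dbl], tot[src1])
  # rates must respect the precondition
  bad <- small_sim_config(seed = 1, outlier_fraction = 0.3,
                          doublet_fraction = 0.3)
  expect_error(inject_qc_artifacts(simulate_branching_lineage(cfg0), bad),
               "0.5")
})

test_that("degenerate configurations are rejected", {
  expect_error(small_sim_config(branch_prob_wt = NaN), "probability")
  expect_error(small_sim_config(branch_prob_wt = 1.2), "probability")
  expect_error(small_sim_config(beta = 0), "rates")
  expect_error(small_sim_config(populations = data.frame(
    name = "X", branch = "pre", t0 = 0.5, t1 = 0.5)), "interval")
  expect_error(small_sim_config(n_genes = 10), "n_genes")
})

test_that("doublet totals equal the sum of their source cells exactly", {
  # direct construction check on a tiny deterministic case
  cfg <- sim_config(n_samples_per_genotype = 1, n_cells_per_sample = 60,
                    n_genes = 180, n_program = 10, n_decoys = 10,
                    doublet_fraction = 0.1, seed = 13)
  sim0 <- simulate_branching_lineage(cfg)
  sim <- inject_qc_artifacts(sim0, cfg)
  meta <- sim$cm$cell_meta
  # reconstruct each doublet by redoing the seeded draw
  set.seed(cfg$seed + 7919L)
  n <- ncol(sim0$cm$counts)
  n_dbl <- round(0.1 * n)
  for (i in seq_len(n_dbl)) {
    pair <- sample.int(n, 2)
    dbl_col <- which(meta$artifact == "doublet")[i]
    expect_equal(
      as.numeric(sim$cm$counts[, dbl_col]),
      as.numeric(sim0$cm$counts[, pair[1]] + sim0$cm$counts[, pair[2]]))
  }
})
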