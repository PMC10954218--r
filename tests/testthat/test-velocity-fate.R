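test_that("velocity is near zero at steady state and positive during induction", {
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 400,
                    n_genes = 220, n_program = 20, n_decoys = 20, seed = 15)
  sim <- simulate_branching_lineage(cfg)
  vm <- estimate_velocity(sim$cm$spliced, sim$cm$unspliced, k_smooth = 15)
  gm <- sim$cm$gene_meta
  role <- gm$role[match(vm$fitted_genes, gm$gene)]
  lt <- sim$cm$cell_meta$latent_time
  br <- sim$cm$cell_meta$branch
  # decoy genes have constant transcription: mean velocity ~ 0 relative
  # to their expression scale
  decoy <- which(role == "decoy")
  rel <- abs(rowMeans(vm$velocity[decoy, ])) /
    (rowMeans(vm$Mu[vm$fitted_genes[decoy], ]) + 0.1)
  expect_lt(median(rel), 0.1)
  # fate-A drivers are being induced in early fate-A cells: v > 0 there
  indA <- which(role == "driver_A")
  early_a <- br == "A" & lt > 0.5 & lt < 0.75
  frac_pos <- mean(vm$velocity[indA, early_a] > 0)
  expect_gt(frac_pos, 0.6)
  expect_gt(mean(vm$velocity[indA, early_a]), 0)
})

test_that("the degradation/splicing ratio is recovered within 10% at low noise", {
  # one gene at two steady states, near-Poisson counts
  set.seed(8)
  n <- 2000
  true_ratio <- 0.5
  s_mol <- c(rep(40, n / 2), rep(8, n / 2))
  u_mol <- true_ratio * s_mol
  spliced <- matrix(rpois(2 * n, rep(s_mol, each = 2)), 2, n)
  unspliced <- matrix(rpois(2 * n, rep(u_mol, each = 2)), 2, n)
  dimnames(spliced) <- dimnames(unspliced) <-
    list(c("gA", "gB"), paste0("c", 1:n))
  emb <- cbind(s_mol + rnorm(n), rnorm(n))
  for (method in c("ratio", "extreme")) {
    vm <- estimate_velocity(spliced, unspliced, k_smooth = 10,
                            embedding = emb, gamma_method = method)
    expect_lt(abs(vm$gamma[["gA"]] - true_ratio) / true_ratio, 0.1)
  }
})

test_that("velocity transitions are monotone in alignment and handle zero velocity", {
  model <- list(
    Ms = matrix(c(0, 1, -1,
                  0, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("a", "b", "c"))),
    velocity = matrix(c(1, 1, 1,
                        0, 0, 0), 2, 3, byrow = TRUE,
                      dimnames = list(c("g1", "g2"), c("a", "b", "c"))),
    fitted_genes = c("g1", "g2"),
    embedding = cbind(c(0, 1, -1), c(0, 0, 0)))
  T_ <- velocity_transition_matrix(model, k_neighbors = 2, stabilize = FALSE)
  # cell a's velocity points toward b and away from c
  expect_gt(T_[1, 2], T_[1, 3])
  expect_equal(Matrix::rowSums(T_), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # all-zero velocities: uniform rows, flagged
  model0 <- model
  model0$velocity[] <- 0
  T0 <- velocity_transition_matrix(model0, k_neighbors = 2,
                                   stabilize = FALSE)
  expect_equal(length(attr(T0, "zero_velocity_cells")), 3)
  expect_true(all(abs(T0@x - 0.5) < 1e-12))
})

test_that("transition mass flows from earlier to later latent times", {
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 400,
                    n_genes = 220, n_program = 20, n_decoys = 20, seed = 16)
  sim <- simulate_branching_lineage(cfg)
  wt <- which(sim$cm$cell_meta$genotype == "wt")
  sub <- subset_cells(sim$cm, wt)
  vm <- estimate_velocity(sub$spliced, sub$unspliced, k_smooth = 15)
  T_ <- velocity_transition_matrix(vm, k_neighbors = 30, kernel_scale = 0.25)
  s <- Matrix::summary(T_)
  lt <- sub$cell_meta$latent_time
  fwd <- sum(s$x[lt[s$j] > lt[s$i]])
  bwd <- sum(s$x[lt[s$j] < lt[s$i]])
  expect_gt(fwd, bwd)
})

test_that("absorption probabilities solve the hand-built chains exactly", {
  # gambler's ruin: A <- 1 -> B with equal odds
  T1 <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(2, 3, 2, 3),
                             x = c(0.5, 0.5, 1, 1), dims = c(3, 3))
  B1 <- absorption_probabilities(T1, c(NA, "A", "B"))
  expect_equal(unname(B1[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # chain A <- 1 <-> 2 -> B: B[1] = (2/3, 1/3) by solving the 2x2 system
  T2 <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 2, 3, 4), j = c(3, 2, 1, 4, 3, 4),
    x = c(0.5, 0.5, 0.5, 0.5, 1, 1), dims = c(4, 4))
  B2 <- absorption_probabilities(T2, c(NA, NA, "A", "B"))
  expect_equal(unname(B2[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(B2[2, ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # terminal rows are their own indicator; all rows sum to 1
  expect_equal(unname(B2[3, ]), c(1, 0))
  expect_true(all(abs(rowSums(B2) - 1) < 1e-12))
  # unreachable transient cells error
  T3 <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 3), x = 1,
                             dims = c(3, 3))
  expect_error(absorption_probabilities(T3, c(NA, NA, "A")), "no path")
})

test_that("the random-walk oracle agrees with the exact solve", {
  # deterministic chain: estimate exactly 1
  Td <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 3), x = 1,
                             dims = c(3, 3))
  Bd <- random_walk_oracle(Td, c(NA, NA, "A"), n_walks = 50, seed = 1)
  expect_equal(unname(Bd[1, 1]), 1)
  # gambler's ruin at 10,000 walks: within 0.02 of 1/2
  T1 <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(2, 3, 2, 3),
                             x = c(0.5, 0.5, 1, 1), dims = c(3, 3))
  B1 <- random_walk_oracle(T1, c(NA, "A", "B"), n_walks = 10000, seed = 2)
  expect_lt(abs(B1[1, "A"] - 0.5), 0.02)
  # a 150-cell simulated velocity graph: exact vs Monte-Carlo
  cfg <- sim_config(n_samples_per_genotype = 1, n_cells_per_sample = 150,
                    n_genes = 220, n_program = 20, n_decoys = 20, seed = 19)
  sim <- simulate_branching_lineage(cfg)
  vm <- estimate_velocity(sim$cm$spliced, sim$cm$unspliced, k_smooth = 10)
  T_ <- velocity_transition_matrix(vm, k_neighbors = 20, kernel_scale = 0.25)
  brv <- sim$cm$cell_meta$branch
  lt <- sim$cm$cell_meta$latent_time
  term <- ifelse(brv != "pre" & lt > 0.8, brv, NA)
  exact <- absorption_probabilities(T_, term)
  mc <- random_walk_oracle(T_, term, n_walks = 1500, seed = 3)
  expect_lt(max(abs(exact - mc)), 0.05)
})

test_that("driver classification follows the correlation rule and recovers truth", {
  # exact copies classify at the boundary rule
  set.seed(23)
  y <- runif(60)
  X <- rbind(copy = y, anti = -y, flat = rep(1, 60),
             noise = rnorm(60))
  colnames(X) <- paste0("c", 1:60)
  fp <- cbind(A = y, B = 1 - y)
  dt <- lineage_drivers(fp, X, "A")
  expect_equal(dt$class[dt$gene == "copy"], "driver")
  expect_equal(dt$rho[dt$gene == "copy"], 1)
  expect_equal(dt$class[dt$gene == "anti"], "antidriver")
  expect_equal(dt$class[dt$gene == "flat"], "neither")
  # Spearman contract: any monotone transform leaves the class unchanged
  X2 <- X; X2["copy", ] <- exp(3 * y)
  dt2 <- lineage_drivers(fp, X2, "A")
  expect_equal(dt2$rho[dt2$gene == "copy"], 1)
})

test_that("simulated drivers are recovered and the branching signature is pure", {
  sim <- simulate_branching_lineage(sim_config(
    n_samples_per_genotype = 2, n_cells_per_sample = 900, seed = 27))
  st <- fate_bias_study(sim, n_subsample = 1500, n_replicates = 1, seed = 27)
  # recompute once at full detail for driver calls
  cm <- sim$cm
  wt <- which(cm$cell_meta$genotype == "wt")
  sub <- subset_cells(cm, wt)
  vm <- estimate_velocity(sub$spliced, sub$unspliced, k_smooth = 15)
  T_ <- velocity_transition_matrix(vm, k_neighbors = 60, kernel_scale = 0.25)
  brv <- sub$cell_meta$branch
  fp <- absorption_probabilities(T_, ifelse(brv %in% c("A", "B"), brv, NA))
  lg <- normalize_log(sub)
  # per-lineage subsets: correlation against fate A over the A lineage
  # (progenitors + A cells), and against fate B over the B lineage -
  # over the pooled cells the two fate probabilities are complementary
  # and every driver of one fate would trivially be an antidriver of the
  # other
  lin_a <- which(brv %in% c("pre", "A"))
  lin_b <- which(brv %in% c("pre", "B"))
  dr_a <- lineage_drivers(fp, lg, "A", cells = lin_a)
  dr_b <- lineage_drivers(fp, lg, "B", cells = lin_b)
  truth <- sim$truth$drivers
  sens <- mean(truth$driver_A %in% dr_a$gene[dr_a$class == "driver"])
  spec <- mean(!(truth$decoy %in% dr_a$gene[dr_a$class == "driver"]))
  # single-seed mechanics check; the multi-seed >= 0.90 recovery claim is
  # asserted in the acceptance suite
  expect_gte(sens, 0.85)
  expect_gte(spec, 0.95)
  sig <- branching_signature(dr_a, dr_b)
  expect_gte(mean(sig$signature %in% truth$bifunctional), 0.9)
  expect_gt(sig$n_shared, 0)
})
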