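test_that("PC selection applies the 2-MAD rule, with fallback and error cases", {
  # one dominant direction: spectrum like {10, 1, 1, ...} -> keep 1
  set.seed(3)
  n <- 200
  latent <- rnorm(n, 0, 10)
  X <- rbind(latent + rnorm(n), latent + rnorm(n), latent + rnorm(n),
             matrix(rnorm(7 * n), 7, n))
  rownames(X) <- paste0("g", 1:10); colnames(X) <- paste0("c", 1:n)
  sel <- select_pcs(X)
  expect_equal(sel$n_selected, 1)
  expect_true(all(diff(sel$explained_variance) < 1e-8))
  # two-eigenvalue spectrum: neither can exceed median + 2 MAD (the gap
  # is exactly 2 MADs), so the fallback keeps the top component and warns
  two <- matrix(rnorm(2 * 100), 2, 100,
                dimnames = list(c("g1", "g2"), paste0("c", 1:100)))
  expect_warning(sel_two <- select_pcs(two), "top")
  expect_equal(sel_two$n_selected, 1)
  expect_error(select_pcs(matrix(1, 5, 10)), "constant")
})

test_that("PC scores reproduce prcomp on a small matrix", {
  set.seed(9)
  X <- matrix(rnorm(30 * 60), 30, 60,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:60)))
  sel <- suppressWarnings(select_pcs(X, k_mad = 0, max_pcs = 5))
  pr <- prcomp(t(X), center = TRUE, scale. = FALSE)
  expect_equal(sel$explained_variance[1:5], unname(pr$sdev[1:5]^2),
               tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(abs(cor(sel$scores[, j], pr$x[, j])), 1, tolerance = 1e-6)
})

test_that("PCA separates the simulated populations", {
  cfg <- seven_pop_config(seed = 2, n_cells_per_sample = 200)
  sim <- simulate_branching_lineage(cfg)
  pe <- normalize_pearson(sim$cm)
  sel <- select_pcs(pe, genes = variable_genes(normalize_log(sim$cm), 150))
  expect_gte(sel$n_selected, 6)
})

test_that("two distant point clouds give exactly their two clusters", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(100 * 2), 100, 2),
               matrix(rnorm(80 * 2, mean = 60), 80, 2))
  sw <- suppressWarnings(cluster_sweep(emb, k_neighbors = 10, k_max = 2,
                                       seed = 1, strict = FALSE))
  lab <- sw$labelings[["2"]]
  truth <- rep(1:2, c(100, 80))
  expect_equal(length(unique(lab)), 2)
  expect_true(all(table(truth, lab) %in% c(0, 80, 100)))
})

test_that("the sweep is deterministic under a fixed seed", {
  set.seed(8)
  emb <- matrix(rnorm(250 * 3), 250, 3)
  a <- suppressWarnings(cluster_sweep(emb, k_neighbors = 12, k_max = 3,
                                      seed = 5, strict = FALSE))
  b <- suppressWarnings(cluster_sweep(emb, k_neighbors = 12, k_max = 3,
                                      seed = 5, strict = FALSE))
  expect_identical(a$labelings, b$labelings)
})

test_that("cluster-tree entropies match hand-computed values and invariants", {
  # level 2 -> level 3: child 1 wholly from parent 1 (H = 0); child 2
  # 50/50 (H = 1 bit); child 3 75/25 (H ~ 0.811)
  par <- rep(c(1, 2), c(40, 40))
  chi <- c(rep(1, 40),            # all from parent 1
           rep(2, 10), rep(3, 30))
  chi[41:50] <- 2                 # child 2: 10 cells from parent 2
  chi[c(1:10)] <- 2               # ... and 10 from parent 1 -> 50/50
  chi[51:80] <- 3
  chi[11:20] <- 3                 # child 3: 10 of 40 from parent 1 -> 25/75
  tree <- build_cluster_tree(list("2" = par, "3" = chi))
  h <- tree$node_entropy
  expect_equal(h$H_bits[h$level == 3 & h$node == 1], 0)
  expect_equal(h$H_bits[h$level == 3 & h$node == 2], 1)
  expect_equal(h$H_bits[h$level == 3 & h$node == 3],
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-9)
  expect_equal(h$H_bits[h$level == 3 & h$node == 3], 0.811, tolerance = 1e-3)
  # proportions per child sum to 1; entropies bounded by log2(K_parent)
  sums <- tapply(tree$edges$proportion, tree$edges$child, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(h$H_bits >= 0 & h$H_bits <= log2(2) + 1e-12))
})

test_that("cluster-number selection follows the entropy threshold rule", {
  # perfectly nested: all H = 0 -> K* = K_max
  nested <- list("2" = rep(1:2, each = 40),
                 "3" = rep(c(1, 2, 3), c(40, 20, 20)),
                 "4" = rep(1:4, each = 20))
  sel <- select_cluster_number(build_cluster_tree(nested))
  expect_equal(sel$k, 4)
  # unstable level 4 (children mixing parents) -> K* = 3
  mixed4 <- rep(1:4, 20)          # scrambles across the level-3 parents
  unstable <- list("2" = rep(1:2, each = 40),
                   "3" = rep(c(1, 2, 3), c(40, 20, 20)),
                   "4" = mixed4)
  sel2 <- select_cluster_number(build_cluster_tree(unstable))
  expect_equal(sel2$k, 3)
  expect_equal(nrow(sel2$curve), 3)
})

test_that("seven well-separated populations are recovered at K = 7 across seeds", {
  # stability study scaled to a handful of seeds; the full 20-seed version
  # runs in the acceptance suite
  hits <- 0; aris <- c()
  for (seed in 1:5) {
    st <- cluster_number_study(seed = seed)
    hits <- hits + (st$k == 7)
    aris <- c(aris, st$ari7)
  }
  expect_gte(hits, 4)
  expect_gte(mean(aris), 0.9)
})

test_that("every cluster at the chosen K is marked by at least one significant gene", {
  cfg <- seven_pop_config(seed = 3, n_cells_per_sample = 150)
  sim <- simulate_branching_lineage(cfg)
  lg <- normalize_log(sim$cm)
  pe <- normalize_pearson(sim$cm)
  sel <- select_pcs(pe, genes = variable_genes(lg, 150))
  cons <- consensus_cluster_number(sel, k_neighbors = 15, k_max = 9,
                                   n_replicates = 2, seed = 3)
  labels <- cons$labels
  expect_false(is.null(labels))
  for (cl in unique(labels)) {
    res <- mann_whitney_dgea(lg, which(labels == cl), which(labels != cl))
    expect_gt(sum(res$Q < 0.05 & res$direction == "up"), 0)
  }
})
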