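#' Simulated seven-population configuration
#'
#' The benchmark configuration for cluster-number selection: one
#' progenitor continuum plus six compact, well-separated derived
#' populations (seven populations in all), with fast kinetics so marker
#' boundaries are crisp and inter-population gaps are unpopulated.
#'
#' @param seed simulator seed.
#' @param n_cells_per_sample cells per library (2 samples per genotype).
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{\link{sim_config}}.
#' @export
seven_population_config <- function(seed = 1, n_cells_per_sample = 220, ...) {
  pops <- data.frame(
    name = c("Prog", paste0("P", 2:7)), branch = "pre",
    t0 = c(0, 0.30 + (0:5) * 0.12),
    t1 = c(0.20, 0.35 + (0:5) * 0.12))
  sim_config(n_samples_per_genotype = 2,
             n_cells_per_sample = n_cells_per_sample,
             n_genes = 260, populations = pops, branch_time = 1,
             n_markers_per_pop = 10, n_drivers_per_fate = 0,
             n_bifunctional = 0, n_program = 10, n_decoys = 20,
             marker_strength = 8, beta = 40, gamma_range = c(15, 25),
             alpha_meanlog = log(60), seed = seed, ...)
}

#' Cluster-number recovery study
#'
#' Simulates the seven-population benchmark, normalizes, selects principal
#' components, and picks the cluster number by consensus total-entropy
#' stable-chain selection over replicate sweeps. Returns the chosen K and
#' the adjusted Rand index of the K = 7 labeling against the true
#' populations.
#'
#' @param seed simulator and sweep seed.
#' @param n_var_genes variable genes used.
#' @param k_max sweep ceiling.
#' @param epsilon_bits consensus entropy threshold (total bits).
#' @param n_cells_per_sample as \code{\link{seven_population_config}}.
#' @return list(k, ari7, curve).
#' @export
cluster_number_study <- function(seed = 1, n_var_genes = 150, k_max = 10,
                                 epsilon_bits = 0.4,
                                 n_cells_per_sample = 220) {
  cfg <- seven_population_config(seed = seed,
                                 n_cells_per_sample = n_cells_per_sample)
  sim <- simulate_branching_lineage(cfg)
  pe <- normalize_pearson(sim$cm)
  vg <- variable_genes(normalize_log(sim$cm), n_var_genes)
  sel <- select_pcs(pe, genes = vg)
  cons <- consensus_cluster_number(sel, k_neighbors = 15, k_max = k_max,
                                   seed = seed,
                                   epsilon_bits = epsilon_bits)
  ari7 <- NA_real_
  lab7 <- NULL
  for (sw in cons$sweeps)
    if (is.null(lab7) && !is.null(sw$labelings[["7"]]))
      lab7 <- sw$labelings[["7"]]
  if (!is.null(lab7)) {
    truth <- as.integer(factor(sim$cm$cell_meta$population))
    ari7 <- adjusted_rand(truth, lab7)
  }
  list(k = cons$k, ari7 = ari7, curve = cons$curve)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer or factor labelings of the same cells.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2))
  cb <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ra * cb / choose(n, 2)
  (s - expected) / ((ra + cb) / 2 - expected)
}

#' Absorption-probability oracle-equivalence study
#'
#' Simulates a ~300-cell branching dataset with three terminal fates
#' (two heart-field-like subfates plus paraxial mesoderm), builds the
#' velocity-directed transition graph, and compares the exact linear-solve
#' fate probabilities with the Monte-Carlo random-walk estimate.
#'
#' @param seed simulator seed.
#' @param mc_seed walk seed.
#' @param n_walks walks per transient cell (default 5000).
#' @return list(max_abs_diff, max_row_sum_err_exact, max_row_sum_err_mc,
#'   n_cells, n_transient).
#' @export
absorption_oracle_study <- function(seed = 101, mc_seed = 1,
                                    n_walks = 5000) {
  pops <- data.frame(name = c("NMP", "FHF", "SHF", "PM"),
                     branch = c("pre", "A", "A", "B"),
                     t0 = c(0, 0.05, 0.05, 0.05),
                     t1 = c(0.05, 1, 1, 1))
  cfg <- sim_config(n_samples_per_genotype = 1, n_cells_per_sample = 300,
                    populations = pops, branch_time = 0.05, n_genes = 300,
                    seed = seed)
  sim <- simulate_branching_lineage(cfg)
  sub <- subset_cells(sim$cm, which(sim$cm$cell_meta$genotype == "wt"))
  vm <- estimate_velocity(sub$spliced, sub$unspliced, k_smooth = 15)
  T_ <- velocity_transition_matrix(vm, k_neighbors = 30,
                                   kernel_scale = 0.25)
  meta <- sub$cell_meta
  term <- ifelse(meta$latent_time > 0.6, meta$population, NA)
  exact <- absorption_probabilities(T_, term)
  mc <- random_walk_oracle(T_, term, n_walks = n_walks, seed = mc_seed)
  list(max_abs_diff = max(abs(exact - mc)),
       max_row_sum_err_exact = max(abs(rowSums(exact) - 1)),
       max_row_sum_err_mc = max(abs(rowSums(mc) - 1)),
       n_cells = ncol(sub$counts), n_transient = sum(is.na(term)))
}

#' Driver-recovery study
#'
#' Simulates the default branching experiment, computes wild-type fate
#' probabilities, classifies drivers per lineage subset at the 0.25
#' correlation rule, and scores recovery against the generative truth.
#'
#' @param seed simulator seed.
#' @param n_cells_per_sample cells per library (2 samples per genotype).
#' @return list(sensitivity, specificity, signature_purity, n_signature).
#' @export
driver_recovery_study <- function(seed = 27, n_cells_per_sample = 900) {
  sim <- simulate_branching_lineage(sim_config(
    n_samples_per_genotype = 2, n_cells_per_sample = n_cells_per_sample,
    seed = seed))
  cm <- sim$cm
  sub <- subset_cells(cm, which(cm$cell_meta$genotype == "wt"))
  vm <- estimate_velocity(sub$spliced, sub$unspliced, k_smooth = 15)
  T_ <- velocity_transition_matrix(vm, k_neighbors = 60,
                                   kernel_scale = 0.25)
  brv <- sub$cell_meta$branch
  fp <- absorption_probabilities(T_, ifelse(brv %in% c("A", "B"), brv, NA))
  lg <- normalize_log(sub)
  dr_a <- lineage_drivers(fp, lg, "A", cells = which(brv %in% c("pre", "A")))
  dr_b <- lineage_drivers(fp, lg, "B", cells = which(brv %in% c("pre", "B")))
  truth <- sim$truth$drivers
  called <- dr_a$gene[dr_a$class == "driver"]
  sig <- branching_signature(dr_a, dr_b)
  list(sensitivity = mean(truth$driver_A %in% called),
       specificity = mean(!(truth$decoy %in% called)),
       signature_purity = if (sig$n_shared > 0)
         mean(sig$signature %in% truth$bifunctional) else NA_real_,
       n_signature = sig$n_shared)
}

#' Label-transfer fidelity study
#'
#' Transfer accuracy of anchor-based projection on the well-separated
#' seven-population benchmark (mutant cells labeled in wild-type space,
#' scored against the true populations).
#'
#' @param seed simulator seed.
#' @return list(accuracy, n_query).
#' @export
transfer_accuracy_study <- function(seed = 65) {
  cfg <- seven_population_config(seed = seed, n_cells_per_sample = 180)
  sim <- simulate_branching_lineage(cfg)
  lg <- normalize_log(sim$cm)
  geno <- sim$cm$cell_meta$genotype
  truth <- sim$cm$cell_meta$population
  vg <- variable_genes(lg, 150)
  anchors <- find_anchors(lg[, geno == "wt"], lg[, geno == "mut"],
                          genes = vg)
  res <- transfer_labels(anchors, truth[geno == "wt"])
  list(accuracy = mean(res$label == truth[geno == "mut"]),
       n_query = sum(geno == "mut"))
}

#' Forward/reverse projection concordance study
#'
#' On the branching two-genotype experiment, projects mutant cells onto
#' the wild-type populations and wild-type cells onto independently
#' labeled mutant populations, then checks that the composition deltas of
#' the two fate populations agree in sign between directions.
#'
#' @param seed simulator seed.
#' @param shuffled permute genotype labels first (negative control).
#' @return list(fates_agree, max_abs_delta, table).
#' @export
reverse_projection_study <- function(seed = 81, shuffled = FALSE) {
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 400,
                    n_genes = 220, n_program = 20, n_decoys = 20,
                    seed = seed)
  sim <- simulate_branching_lineage(cfg)
  lg <- normalize_log(sim$cm)
  meta <- sim$cm$cell_meta
  geno <- meta$genotype
  if (shuffled) {
    set.seed(seed)
    geno <- sample(geno)
  }
  wt <- geno == "wt"; mut <- !wt
  vg <- variable_genes(lg, 150)
  fa <- find_anchors(lg[, wt], lg[, mut], genes = vg)
  fwd <- transfer_labels(fa, meta$population[wt])
  ra <- find_anchors(lg[, mut], lg[, wt], genes = vg)
  rev_ <- transfer_labels(ra, meta$population[mut])
  chk <- reverse_projection_check(meta$population[wt], fwd$label,
                                  meta$population[mut], rev_$label)
  fates <- chk$table[chk$table$population %in% c("FHF", "PM"), ]
  list(fates_agree = all(fates$sign_agree),
       max_abs_delta = max(abs(chk$table$delta_forward)),
       table = chk$table)
}

#' Pseudotime-recovery study
#'
#' Diffusion-flood pseudotime on the branching experiment, scored by
#' Spearman correlation against the generative latent time.
#'
#' @param seed simulator seed.
#' @param n_floods flood repetitions.
#' @return list(spearman, n_cells).
#' @export
pseudotime_recovery_study <- function(seed = 12, n_floods = 60) {
  cfg <- sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 400,
                    n_genes = 220, n_program = 20, n_decoys = 20,
                    seed = seed)
  sim <- simulate_branching_lineage(cfg)
  pe <- normalize_pearson(sim$cm)
  sel <- select_pcs(pe, genes = variable_genes(normalize_log(sim$cm), 150))
  T_ <- diffusion_transitions(sel$scores, k_neighbors = 15)
  roots <- order(sim$cm$cell_meta$latent_time)[1:20]
  res <- flood_pseudotime(T_, roots, n_floods = n_floods, seed = seed)
  list(spearman = stats::cor(res$pseudotime,
                             sim$cm$cell_meta$latent_time,
                             method = "spearman"),
       n_cells = ncol(sim$cm$counts))
}
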