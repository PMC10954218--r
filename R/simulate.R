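#' Configuration for the branching-lineage simulator
#'
#' Describes a two-genotype, branching mesodermal lineage: cells move along
#' a latent time in [0, 1]; at \code{branch_time} each cell commits to fate
#' A (heart-field-like) with a genotype-specific probability, otherwise to
#' fate B (paraxial-mesoderm-like). Per-gene transcription rates
#' \eqn{\alpha(t)} are piecewise linear in latent time; unspliced and
#' spliced abundances follow \eqn{du/dt = \alpha - \beta u},
#' \eqn{ds/dt = \beta u - \gamma s}, integrated on a fixed grid, and counts
#' are negative-binomial draws around library-size-scaled expectations.
#'
#' Gene roles built into the default architecture:
#' population markers (on only within their population), fate-A/fate-B
#' driver genes (transcription ramps up along the matching branch),
#' bifunctional genes (up along A, down along B - the generative lineage
#' branching signature), decoy genes (constant, fate-independent), a
#' persistent-regulator gene whose transcription decays along latent time
#' in the "wt" profile but persists in the "mut" profile, a chromosomally
#' ordered positional gene cluster with staged activation times, and
#' flagged mitochondrial genes.
#'
#' @param n_samples_per_genotype embryos (libraries) per genotype.
#' @param n_cells_per_sample cells per library.
#' @param n_genes total genes, including all special roles.
#' @param populations data.frame(name, branch, t0, t1) with branch in
#'   \{"pre","A","B"\}; intervals within [0,1] and non-empty.
#' @param branch_time latent time of fate commitment, in (0, 1].
#' @param branch_prob_wt,branch_prob_mut probability of fate A at the
#'   branch point for each genotype.
#' @param n_markers_per_pop,n_drivers_per_fate,n_bifunctional,n_program,n_decoys,n_mito
#'   gene-architecture block sizes (\code{n_bifunctional} genes per
#'   direction); \code{n_program} genes form a shared
#'   differentiation program ramping monotonically along latent time on
#'   both branches (two thirds up, one third down), the common "forward"
#'   axis of the manifold.
#' @param marker_strength fold elevation of a marker's transcription inside
#'   its own population.
#' @param regulator_profile list(wt = c(start, end), mut = c(start, end)):
#'   transcription-rate levels of the persistent-regulator gene at latent
#'   time 0 and 1, interpolated linearly.
#' @param positional_cluster list(n, chrom, t_first, t_last, width): genes
#'   switching on at evenly staged latent times, ordered 5' to 3' along one
#'   chromosome.
#' @param genotype_driver_factor multiplier applied to driver and
#'   bifunctional transcription rates in the mutant.
#' @param priming_window,priming_factor lineage priming: progenitors
#'   within \code{priming_window} of the branch point up-regulate the
#'   drivers and bifunctional genes of their (latent) future fate by a
#'   factor ramping to \code{priming_factor}; 0 disables priming.
#' @param alpha_meanlog,alpha_sdlog lognormal baseline transcription rates.
#' @param beta splicing rate (shared).
#' @param gamma_range per-gene degradation rates drawn uniformly here.
#' @param libsize_lognorm_params c(meanlog, sdlog) of per-cell library
#'   factors.
#' @param sample_depth_sdlog lognormal sd of per-sample depth factors
#'   (inter-library depth imbalance).
#' @param nb_dispersion negative-binomial size parameter theta (Inf gives
#'   the Poisson limit).
#' @param unspliced_scale capture efficiency of unspliced relative to
#'   spliced molecules.
#' @param mito_target_fraction expected mitochondrial fraction of a clean
#'   cell's transcripts.
#' @param outlier_fraction,doublet_fraction artifact rates used by
#'   \code{\link{inject_qc_artifacts}}.
#' @param discrete_populations snap each cell's latent time to its
#'   population's interval midpoint, turning the continuum into discrete
#'   steady-state populations (for studies of well-separated cell types).
#' @param stage stage label stored in cell metadata.
#' @param seed integer; fully determines the output.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples_per_genotype = 6,
                       n_cells_per_sample = 1000,
                       n_genes = 300,
                       populations = data.frame(
                         name = c("NMP", "FHF", "PM"),
                         branch = c("pre", "A", "B"),
                         t0 = c(0, 0.45, 0.45),
                         t1 = c(0.45, 1, 1)),
                       branch_time = 0.45,
                       branch_prob_wt = 0.60,
                       branch_prob_mut = 0.45,
                       n_markers_per_pop = 8,
                       n_drivers_per_fate = 20,
                       n_bifunctional = 12,
                       n_program = 30,
                       n_decoys = 30,
                       n_mito = 10,
                       marker_strength = 6,
                       regulator_profile = list(wt = c(4, 0.4), mut = c(4, 3.6)),
                       positional_cluster = list(n = 10, chrom = "chrP",
                                                 t_first = 0.1, t_last = 0.85,
                                                 width = 0.15),
                       genotype_driver_factor = 1,
                       priming_window = 0,
                       priming_factor = 2.5,
                       alpha_meanlog = log(8), alpha_sdlog = 0.6,
                       beta = 5, gamma_range = c(1.5, 4),
                       libsize_lognorm_params = c(0, 0.25),
                       sample_depth_sdlog = 0.3,
                       nb_dispersion = 2,
                       unspliced_scale = 0.5,
                       mito_target_fraction = 0.05,
                       outlier_fraction = 0,
                       doublet_fraction = 0,
                       discrete_populations = FALSE,
                       stage = "LB",
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$branch_prob_wt, cfg$branch_prob_mut,
             cfg$outlier_fraction, cfg$doublet_fraction,
             cfg$mito_target_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("degenerate probability in sim_config (must be finite, in [0,1])")
  if (cfg$beta <= 0 || any(cfg$gamma_range <= 0))
    stop("kinetic rates beta, gamma must be > 0")
  p <- cfg$populations
  if (!all(c("name", "branch", "t0", "t1") %in% names(p)))
    stop("populations needs columns name, branch, t0, t1")
  if (!all(p$branch %in% c("pre", "A", "B")))
    stop("population branch must be 'pre', 'A' or 'B'")
  if (any(p$t0 < 0) || any(p$t1 > 1) || any(p$t1 <= p$t0))
    stop("empty or out-of-range population interval")
  if (cfg$branch_time <= 0 || cfg$branch_time > 1)
    stop("branch_time must be in (0, 1]")
  n_special <- nrow(p) * cfg$n_markers_per_pop + 2 * cfg$n_drivers_per_fate +
    2 * cfg$n_bifunctional + cfg$n_program + cfg$n_decoys + cfg$n_mito +
    cfg$positional_cluster$n + 1
  if (cfg$n_genes < n_special)
    stop("n_genes too small for the configured gene architecture (need >= ",
         n_special, ")")
  invisible(cfg)
}

#' Integrate spliced/unspliced kinetics on a fixed latent-time grid
#'
#' Solves du/dt = alpha(t) - beta*u, ds/dt = beta*u - gamma*s by exact
#' per-step exponential updates with alpha held at its left-grid value,
#' starting from the steady state of alpha(0). Vectorized over genes:
#' \code{alpha} may be a genes x grid matrix.
#'
#' @param alpha vector (length n_grid) or genes x n_grid matrix of
#'   transcription rates on the grid.
#' @param beta splicing rate (scalar).
#' @param gamma degradation rate, scalar or per-gene vector.
#' @param n_grid number of grid points on [0, 1].
#' @return list(u, s): genes x n_grid matrices, and \code{tgrid}.
#' @export
kinetics_trajectory <- function(alpha, beta, gamma, n_grid = 200) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  stopifnot(ncol(alpha) == n_grid, beta > 0, all(gamma > 0))
  G <- nrow(alpha)
  gamma <- rep_len(gamma, G)
  dt <- 1 / (n_grid - 1)
  u <- s <- matrix(0, G, n_grid)
  u[, 1] <- alpha[, 1] / beta
  s[, 1] <- alpha[, 1] / gamma
  eb <- exp(-beta * dt)
  eg <- exp(-gamma * dt)
  for (k in seq_len(n_grid - 1)) {
    u[, k + 1] <- u[, k] * eb + (alpha[, k] / beta) * (1 - eb)
    s[, k + 1] <- s[, k] * eg + (beta * u[, k] / gamma) * (1 - eg)
  }
  list(u = u, s = s, tgrid = seq(0, 1, length.out = n_grid))
}

# ---- gene architecture -----------------------------------------------------

# Assign roles, rates and genomic coordinates to the n_genes genes.
build_gene_table <- function(cfg) {
  npop <- nrow(cfg$populations)
  roles <- c(
    rep(paste0("marker_", cfg$populations$name), each = cfg$n_markers_per_pop),
    rep("driver_A", cfg$n_drivers_per_fate),
    rep("driver_B", cfg$n_drivers_per_fate),
    rep("bifunctional_A", cfg$n_bifunctional),
    rep("bifunctional_B", cfg$n_bifunctional),
    rep("program_up", ceiling(2 * cfg$n_program / 3)),
    rep("program_down", cfg$n_program - ceiling(2 * cfg$n_program / 3)),
    rep("decoy", cfg$n_decoys),
    "regulator",
    rep("positional", cfg$positional_cluster$n),
    rep("mito", cfg$n_mito))
  roles <- c(roles, rep("baseline", cfg$n_genes - length(roles)))
  g <- data.frame(
    gene = sprintf("gene%04d", seq_len(cfg$n_genes)),
    role = roles, stringsAsFactors = FALSE)
  g$marker_pop <- ifelse(startsWith(g$role, "marker_"),
                         sub("^marker_", "", g$role), NA_character_)
  g$mito <- g$role == "mito"
  g$gene[g$role == "mito"] <- sprintf("mt-gene%02d", seq_len(cfg$n_mito))
  g$cluster_position <- NA_integer_
  g$cluster_position[g$role == "positional"] <- seq_len(cfg$positional_cluster$n)
  # kinetic rates and baseline transcription
  g$beta <- cfg$beta
  g$gamma <- stats::runif(cfg$n_genes, cfg$gamma_range[1], cfg$gamma_range[2])
  g$alpha0 <- stats::rlnorm(cfg$n_genes, cfg$alpha_meanlog, cfg$alpha_sdlog)
  # population markers are fast genes: switch-like on/off boundaries need
  # short kinetic lags, or populations blur into each other
  fast <- startsWith(g$role, "marker_") | g$role == "regulator"
  g$gamma[fast] <- cfg$gamma_range[2]
  # fate-informative genes are fast responders: their expression must
  # track the post-branch transcription ramps within a fraction of the
  # branch arm, or rank correlations with fate probabilities are diluted
  fate_roles <- c("driver_A", "driver_B", "bifunctional_A", "bifunctional_B")
  g$gamma[g$role %in% fate_roles] <- 2 * cfg$gamma_range[2]
  # markers carry each population's identity: fixed amplitude, so no
  # population is crippled by an unlucky lognormal draw
  g$alpha0[startsWith(g$role, "marker_")] <- exp(cfg$alpha_meanlog)
  # the persistent regulator is a well-expressed factor: its decay (or
  # persistence) must be visible above the count noise floor
  g$alpha0[g$role == "regulator"] <- 4 * g$alpha0[g$role == "regulator"]
  # fate-informative genes are likewise well expressed, or their
  # correlation with fate probabilities drowns in sampling noise
  fate_genes <- g$role %in% c("driver_A", "driver_B",
                              "bifunctional_A", "bifunctional_B")
  g$alpha0[fate_genes] <- 3 * g$alpha0[fate_genes]
  # scale mito transcription so the expected mito fraction hits the target
  mito <- g$mito
  steady <- g$alpha0 / g$gamma
  tgt <- cfg$mito_target_fraction
  if (any(mito) && tgt > 0) {
    fac <- (tgt / (1 - tgt)) * sum(steady[!mito]) / sum(steady[mito])
    g$alpha0[mito] <- g$alpha0[mito] * fac
  }
  # genomic coordinates: positional cluster ordered along one chromosome,
  # everything else round-robin on chr1..chr5
  g$chromosome <- rep(paste0("chr", 1:5), length.out = cfg$n_genes)
  g$strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  g$tss <- 10000L * seq_len(cfg$n_genes)
  pos <- which(g$role == "positional")
  g$chromosome[pos] <- cfg$positional_cluster$chrom
  g$strand[pos] <- "+"
  g$tss[pos] <- 50000L + 10000L * seq_along(pos)
  g
}

# Piecewise-linear ramp helper on the grid
ramp_up <- function(tgrid, t_on, width) pmin(1, pmax(0, (tgrid - t_on) / width))

# alpha(t) on the grid for every gene, under a given population context and
# genotype. The context supplies the ancestral population at each grid time
# (pre-branch history plus the population's own branch), so expression is
# continuous across the branch point.
alpha_grid_for_context <- function(cfg, genes, pop_name, genotype, tgrid) {
  pops <- cfg$populations
  this <- pops[pops$name == pop_name, ]
  path <- if (this$branch == "pre") "A" else this$branch
  # ancestral population at each grid point
  anc <- character(length(tgrid))
  for (i in seq_along(tgrid)) {
    t <- tgrid[i]
    cand <- pops[(pops$branch == "pre" | pops$branch == this$branch) &
                   pops$t0 <= t & t < pops$t1 + 1e-12, , drop = FALSE]
    if (pop_name %in% cand$name) anc[i] <- pop_name
    else if (nrow(cand) > 0) anc[i] <- cand$name[which.max(cand$t0)]
    else anc[i] <- pops$name[which.min(pmin(abs(pops$t0 - t), abs(pops$t1 - t)))]
  }
  G <- nrow(genes)
  A <- matrix(genes$alpha0, G, length(tgrid))
  low <- 0.05
  bt <- cfg$branch_time
  post <- ramp_up(tgrid, bt, 0.1)           # 0 before branch, 1 after
  for (r in seq_len(G)) {
    role <- genes$role[r]
    a0 <- genes$alpha0[r]
    if (startsWith(role, "marker_")) {
      mp <- genes$marker_pop[r]
      on <- as.numeric(anc == mp)
      # soften edges one grid-step for kinetic smoothness
      A[r, ] <- a0 * (low + (cfg$marker_strength - low) * on)
    } else if (role == "driver_A" || role == "driver_B") {
      want <- if (role == "driver_A") "A" else "B"
      if (path == want) {
        A[r, ] <- a0 * (low + (4 - low) * ramp_up(tgrid, bt, 0.1))
      } else {
        # mild shared-differentiation component on the sibling branch:
        # plain drivers rise with their own fate but do not fall below
        # baseline on the sibling, so they are not sibling antidrivers
        # (that pattern is reserved for the bifunctional genes)
        A[r, ] <- a0 * (low + (1.75 - low) * ramp_up(tgrid, bt, 0.1))
      }
    } else if (role == "bifunctional_A" || role == "bifunctional_B") {
      up_path <- if (role == "bifunctional_A") "A" else "B"
      if (path == up_path)
        A[r, ] <- a0 * (1 + 3 * ramp_up(tgrid, bt, 0.1))
      else
        A[r, ] <- a0 * pmax(low, 1 - 0.95 * ramp_up(tgrid, bt, 0.1))
    } else if (role == "program_up") {
      A[r, ] <- a0 * (low + (3 - low) * pmin(tgrid / 0.75, 1))
    } else if (role == "program_down") {
      A[r, ] <- a0 * (3 - (3 - low) * pmin(tgrid / 0.75, 1))
    } else if (role == "regulator") {
      prof <- cfg$regulator_profile[[genotype]]
      A[r, ] <- a0 * (prof[1] + (prof[2] - prof[1]) * tgrid) / prof[1]
      A[r, ] <- pmax(A[r, ], 1e-3)
    } else if (role == "positional") {
      # staged on/off pulse: switches on at its positional time, stays on
      # for twice the ramp width, then decays
      k <- genes$cluster_position[r]
      pc <- cfg$positional_cluster
      t_on <- pc$t_first + (k - 1) / max(1, pc$n - 1) * (pc$t_last - pc$t_first)
      pulse <- ramp_up(tgrid, t_on, pc$width) -
        ramp_up(tgrid, t_on + 2 * pc$width, pc$width)
      A[r, ] <- a0 * (low + (3 - low) * pmax(pulse, 0))
    }
    # decoy, mito, baseline: constant alpha0
  }
  if (genotype == "mut" && cfg$genotype_driver_factor != 1) {
    dr <- genes$role %in% c("driver_A", "driver_B", "bifunctional")
    A[dr, ] <- A[dr, ] * cfg$genotype_driver_factor
  }
  A
}

# ---- main simulator --------------------------------------------------------

#' Simulate a two-genotype branching-lineage scRNA-seq experiment
#'
#' Draws cells along latent time, commits each post-branch cell to fate A
#' with the genotype's branch probability, computes expected spliced and
#' unspliced abundances from the per-gene kinetics, and samples
#' negative-binomial counts with per-cell library scaling. The output
#' carries full ground truth (population labels, latent times, branch,
#' generative fate probabilities, driver gene sets) so downstream methods
#' can be validated by parameter recovery.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_grid latent-time grid resolution for the kinetics integrator.
#' @param keep_expectation store the expected spliced/unspliced matrices
#'   (dense) in the output, enabling \code{\link{resample_counts}}.
#' @return an object of class \code{sim_output}: list with \code{cm} (a
#'   \code{\link{count_matrix}} with spliced/unspliced layers; cell
#'   metadata columns population, latent_time, branch, artifact),
#'   \code{truth} (list: fate_prob matrix cells x c(A,B), drivers list),
#'   and \code{config}.
#' @export
simulate_branching_lineage <- function(config, n_grid = 200,
                                       keep_expectation = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- build_gene_table(config)
  tgrid <- seq(0, 1, length.out = n_grid)
  pops <- config$populations
  genotypes <- c("wt", "mut")
  bprob <- c(wt = config$branch_prob_wt, mut = config$branch_prob_mut)

  # trajectories per (population context, genotype)
  traj <- list()
  for (g in genotypes) for (p in pops$name) {
    A <- alpha_grid_for_context(config, genes, p, g, tgrid)
    traj[[paste(g, p)]] <- kinetics_trajectory(A, config$beta, genes$gamma,
                                               n_grid)
  }

  n_per <- config$n_cells_per_sample
  cells <- list()
  for (g in genotypes) for (s in seq_len(config$n_samples_per_genotype)) {
    sample_id <- paste0(g, s)
    t <- stats::runif(n_per)
    fate <- ifelse(stats::runif(n_per) < bprob[[g]], "A", "B")
    # cells live only on populated latent-time intervals: redraw times
    # falling into coverage gaps (no-op when populations tile [0, 1])
    covered <- function(tv, fv) {
      ok <- logical(length(tv))
      for (i in seq_along(tv)) {
        br <- if (tv[i] < config$branch_time) "pre" else fv[i]
        ok[i] <- any(pops$branch == br & pops$t0 <= tv[i] &
                       tv[i] < pops$t1 + 1e-12)
      }
      ok
    }
    for (round in 1:50) {
      bad <- which(!covered(t, fate))
      if (!length(bad)) break
      t[bad] <- stats::runif(length(bad))
    }
    branch <- ifelse(t < config$branch_time, "pre", fate)
    pop <- character(n_per)
    for (i in seq_len(n_per)) {
      br <- branch[i]
      cand <- if (br == "pre") pops[pops$branch == "pre" &
                                      pops$t0 <= t[i] & t[i] < pops$t1 + 1e-12, ]
              else pops[pops$branch == br &
                          pops$t0 <= t[i] & t[i] < pops$t1 + 1e-12, ]
      if (nrow(cand) == 0) {  # fall back to nearest interval of that branch
        cand <- if (br == "pre") pops[pops$branch == "pre", ]
                else pops[pops$branch == br, ]
        cand <- cand[which.min(pmin(abs(cand$t0 - t[i]), abs(cand$t1 - t[i]))), ]
      }
      pop[i] <- if (nrow(cand) == 1) cand$name
                else cand$name[sample.int(nrow(cand), 1)]
    }
    if (isTRUE(config$discrete_populations)) {
      mid <- (pops$t0 + pops$t1) / 2
      t <- mid[match(pop, pops$name)]
    }
    sf <- stats::rlnorm(1, 0, config$sample_depth_sdlog)
    lf <- sf * stats::rlnorm(n_per, config$libsize_lognorm_params[1],
                             config$libsize_lognorm_params[2])
    cells[[sample_id]] <- data.frame(
      barcode = paste0(sample_id, "_c", seq_len(n_per)),
      sample = sample_id, genotype = g, stage = config$stage,
      population = pop, latent_time = t, branch = branch,
      latent_fate = fate, lib_factor = lf, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, cells)
  rownames(meta) <- NULL
  n_cells <- nrow(meta)
  G <- nrow(genes)

  # expected abundances by trajectory interpolation, grouped by (genotype,
  # population) for vectorization
  mu_s <- matrix(0, G, n_cells)
  mu_u <- matrix(0, G, n_cells)
  for (key in names(traj)) {
    gp <- strsplit(key, " ")[[1]]
    idx <- which(meta$genotype == gp[1] & meta$population == gp[2])
    if (!length(idx)) next
    ti <- meta$latent_time[idx]
    k <- pmin(findInterval(ti, tgrid), n_grid - 1)
    w <- (ti - tgrid[k]) / (tgrid[2] - tgrid[1])
    tr <- traj[[key]]
    mu_s[, idx] <- sweep(tr$s[, k, drop = FALSE], 2, 1 - w, "*") +
      sweep(tr$s[, k + 1, drop = FALSE], 2, w, "*")
    mu_u[, idx] <- sweep(tr$u[, k, drop = FALSE], 2, 1 - w, "*") +
      sweep(tr$u[, k + 1, drop = FALSE], 2, w, "*")
  }
  # lineage priming: progenitors approaching the branch point already
  # up-regulate the drivers of the fate they will adopt, before overt
  # commitment (the observable basis of fate-probability gradients)
  bt <- config$branch_time
  pw <- config$priming_window
  if (pw > 0 && any(meta$branch == "pre")) {
    pf <- 1 + (config$priming_factor - 1) *
      pmax(0, (meta$latent_time - (bt - pw)) / pw)
    for (fa in c("A", "B")) {
      gsel <- genes$role %in% paste0(c("driver_", "bifunctional_"), fa)
      csel <- meta$branch == "pre" & meta$latent_fate == fa
      if (any(gsel) && any(csel)) {
        mu_s[gsel, csel] <- sweep(mu_s[gsel, csel, drop = FALSE], 2,
                                  pf[csel], "*")
        mu_u[gsel, csel] <- sweep(mu_u[gsel, csel, drop = FALSE], 2,
                                  pf[csel], "*")
      }
    }
  }
  mu_s <- sweep(mu_s, 2, meta$lib_factor, "*")
  mu_u <- sweep(mu_u, 2, meta$lib_factor * config$unspliced_scale, "*")

  spliced <- draw_nb(mu_s, config$nb_dispersion)
  unspliced <- draw_nb(mu_u, config$nb_dispersion)
  dimnames(spliced) <- dimnames(unspliced) <- list(genes$gene, meta$barcode)

  gm <- genes[, c("gene", "role", "marker_pop", "mito", "cluster_position",
                  "chromosome", "strand", "tss", "beta", "gamma", "alpha0")]
  meta$artifact <- "none"
  cm <- count_matrix(spliced + unspliced, cell_meta = meta, gene_meta = gm,
                     spliced = Matrix::Matrix(spliced, sparse = TRUE),
                     unspliced = Matrix::Matrix(unspliced, sparse = TRUE))
  fate_prob <- cbind(A = ifelse(meta$branch == "pre", bprob[meta$genotype],
                                as.numeric(meta$branch == "A")),
                     B = ifelse(meta$branch == "pre", 1 - bprob[meta$genotype],
                                as.numeric(meta$branch == "B")))
  rownames(fate_prob) <- meta$barcode
  drivers <- list(
    driver_A = genes$gene[genes$role %in% c("driver_A", "bifunctional_A")],
    driver_B = genes$gene[genes$role %in% c("driver_B", "bifunctional_B")],
    bifunctional = genes$gene[genes$role %in% c("bifunctional_A",
                                                "bifunctional_B")],
    bifunctional_A = genes$gene[genes$role == "bifunctional_A"],
    bifunctional_B = genes$gene[genes$role == "bifunctional_B"],
    decoy = genes$gene[genes$role == "decoy"])
  out <- structure(list(cm = cm, truth = list(fate_prob = fate_prob,
                                              drivers = drivers),
                        config = config), class = "sim_output")
  if (keep_expectation) {
    out$expected_spliced <- mu_s
    out$expected_unspliced <- mu_u
  }
  out
}

draw_nb <- function(mu, theta) {
  n <- length(mu)
  x <- if (is.infinite(theta)) stats::rpois(n, mu)
       else stats::rnbinom(n, size = theta, mu = mu)
  matrix(x, nrow(mu), ncol(mu))
}

#' Redraw counts around a simulation's stored expectations
#'
#' Requires \code{simulate_branching_lineage(..., keep_expectation = TRUE)}.
#' Useful for Monte-Carlo checks of the count model against the closed-form
#' integrator expectations.
#'
#' @param sim a \code{sim_output} with stored expectations.
#' @param seed RNG seed for the redraw.
#' @return list(spliced, unspliced) dense count matrices.
#' @export
resample_counts <- function(sim, seed = 1) {
  if (is.null(sim$expected_spliced))
    stop("simulate with keep_expectation = TRUE first")
  set.seed(seed)
  list(spliced = draw_nb(sim$expected_spliced, sim$config$nb_dispersion),
       unspliced = draw_nb(sim$expected_unspliced, sim$config$nb_dispersion))
}

#' Inject QC artifacts (low-quality outliers and doublets)
#'
#' Appends flagged artifact cells to a simulation: outliers are existing
#' cells with most non-mitochondrial counts thinned away and mitochondrial
#' counts inflated; doublets are plain elementwise sums of two random cells
#' (no depth rescaling, so the count-sum identity holds exactly). Artifact
#' provenance is recorded in \code{cell_meta$artifact}.
#'
#' @param sim a \code{sim_output}.
#' @param config the \code{sim_config} (supplies outlier_fraction,
#'   doublet_fraction and the seed).
#' @return the augmented \code{sim_output}.
#' @export
inject_qc_artifacts <- function(sim, config = sim$config) {
  f_out <- config$outlier_fraction
  f_dbl <- config$doublet_fraction
  if (f_out + f_dbl >= 0.5)
    stop("outlier_fraction + doublet_fraction must be < 0.5")
  if (f_out == 0 && f_dbl == 0) return(sim)
  set.seed(config$seed + 7919L)
  cm <- sim$cm
  n <- ncol(cm$counts)
  n_out <- round(f_out * n)
  n_dbl <- round(f_dbl * n)
  mito <- cm$gene_meta$mito
  new_cols <- list(); new_meta <- list(); new_fp <- list()
  make_cell <- function(cnts, template_i, kind, idx) {
    bc <- paste0(kind, idx, "_", cm$cell_meta$barcode[template_i])
    m <- cm$cell_meta[template_i, , drop = FALSE]
    m$barcode <- bc; m$artifact <- kind
    new_meta[[length(new_meta) + 1]] <<- m
    new_fp[[length(new_fp) + 1]] <<- sim$truth$fate_prob[template_i, , drop = FALSE]
    colnames(cnts) <- bc
    new_cols[[length(new_cols) + 1]] <<- cnts
  }
  layer_names <- c("counts", "spliced", "unspliced")
  new_layers <- stats::setNames(vector("list", 3), layer_names)
  for (ln in layer_names) new_layers[[ln]] <- list()
  if (n_out > 0) {
    tmpl <- sample.int(n, n_out, replace = TRUE)
    for (i in seq_len(n_out)) {
      ci <- tmpl[i]
      for (ln in layer_names) {
        x <- cm[[ln]][, ci, drop = FALSE]
        xv <- as.matrix(x)
        xv[!mito, 1] <- stats::rbinom(sum(!mito), xv[!mito, 1], 0.15)
        xv[mito, 1] <- xv[mito, 1] * 8
        colnames(xv) <- paste0("out", i, "_", cm$cell_meta$barcode[ci])
        new_layers[[ln]][[length(new_layers[[ln]]) + 1]] <- xv
      }
      m <- cm$cell_meta[ci, , drop = FALSE]
      m$barcode <- paste0("out", i, "_", m$barcode); m$artifact <- "outlier"
      new_meta[[length(new_meta) + 1]] <- m
      new_fp[[length(new_fp) + 1]] <- sim$truth$fate_prob[ci, , drop = FALSE]
    }
  }
  if (n_dbl > 0) {
    for (i in seq_len(n_dbl)) {
      pair <- sample.int(n, 2)
      for (ln in layer_names) {
        xv <- as.matrix(cm[[ln]][, pair[1], drop = FALSE]) +
          as.matrix(cm[[ln]][, pair[2], drop = FALSE])
        colnames(xv) <- paste0("dbl", i, "_", cm$cell_meta$barcode[pair[1]])
        new_layers[[ln]][[length(new_layers[[ln]]) + 1]] <- xv
      }
      m <- cm$cell_meta[pair[1], , drop = FALSE]
      m$barcode <- paste0("dbl", i, "_", m$barcode); m$artifact <- "doublet"
      new_meta[[length(new_meta) + 1]] <- m
      new_fp[[length(new_fp) + 1]] <- sim$truth$fate_prob[pair[1], , drop = FALSE]
    }
  }
  add <- lapply(new_layers, function(l) Matrix::Matrix(do.call(cbind, l), sparse = TRUE))
  meta2 <- rbind(cm$cell_meta, do.call(rbind, new_meta))
  rownames(meta2) <- NULL
  cm2 <- count_matrix(cbind(cm$counts, add$counts),
                      cell_meta = meta2, gene_meta = cm$gene_meta,
                      spliced = cbind(cm$spliced, add$spliced),
                      unspliced = cbind(cm$unspliced, add$unspliced))
  sim$cm <- cm2
  sim$truth$fate_prob <- rbind(sim$truth$fate_prob, do.call(rbind, new_fp))
  rownames(sim$truth$fate_prob) <- meta2$barcode
  sim
}
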