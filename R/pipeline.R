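#' Write a count_matrix as 10x-style MTX triplets (plus layers)
#'
#' Writes matrix.mtx, barcodes.tsv, features.tsv, optional
#' spliced.mtx/unspliced.mtx parallel layers, cell metadata, and truth
#' tables if present. Plain text (optionally gzipped).
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param dir output directory (created).
#' @param gzip gzip the MTX files.
#' @return \code{dir}, invisibly.
#' @export
write_mtx_layers <- function(cm, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmm <- function(m, name) {
    f <- file.path(dir, name)
    Matrix::writeMM(m, f)
    if (gzip) {
      con <- gzfile(paste0(f, ".gz"), "wb")
      writeLines(readLines(f), con)
      close(con)
      unlink(f)
    }
  }
  wmm(cm$counts, "matrix.mtx")
  if (!is.null(cm$spliced)) wmm(cm$spliced, "spliced.mtx")
  if (!is.null(cm$unspliced)) wmm(cm$unspliced, "unspliced.mtx")
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count_matrix from MTX triplets
#'
#' @param dir directory containing matrix.mtx(.gz), barcodes.tsv,
#'   features.tsv, and optionally spliced.mtx/unspliced.mtx and
#'   cell_meta.tsv.
#' @return a \code{\link{count_matrix}}.
#' @export
read_mtx_layers <- function(dir) {
  find <- function(name, required = TRUE) {
    for (f in c(file.path(dir, name), file.path(dir, paste0(name, ".gz"))))
      if (file.exists(f)) return(f)
    if (required) stop("missing file: ", file.path(dir, name))
    NULL
  }
  rmm <- function(f) {
    if (endsWith(f, ".gz")) {
      tmp <- tempfile(fileext = ".mtx")
      writeLines(readLines(f), tmp)
      on.exit(unlink(tmp))
      methods::as(Matrix::readMM(tmp), "CsparseMatrix")
    } else methods::as(Matrix::readMM(f), "CsparseMatrix")
  }
  counts <- rmm(find("matrix.mtx"))
  barcodes <- readLines(find("barcodes.tsv"))
  features <- utils::read.table(find("features.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(features$gene, barcodes)
  spliced <- unspliced <- NULL
  sf <- find("spliced.mtx", required = FALSE)
  uf <- find("unspliced.mtx", required = FALSE)
  if (!is.null(sf)) {
    spliced <- rmm(sf)
    if (!identical(dim(spliced), dim(counts)))
      stop("spliced layer shape mismatch")
    dimnames(spliced) <- dimnames(counts)
  }
  if (!is.null(uf)) {
    unspliced <- rmm(uf)
    if (!identical(dim(unspliced), dim(counts)))
      stop("unspliced layer shape mismatch")
    dimnames(unspliced) <- dimnames(counts)
  }
  mf <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(mf))
    utils::read.table(mf, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else NULL
  count_matrix(counts, cell_meta = cell_meta, gene_meta = features,
               spliced = spliced, unspliced = unspliced)
}

#' Pipeline configuration
#'
#' One object holding the simulator configuration and every stage
#' parameter; each random stage derives its own seed deterministically
#' from the global seed. Round-trips losslessly through YAML.
#'
#' @param sim a \code{\link{sim_config}} (its seed is overridden by
#'   \code{seed}).
#' @param seed global seed.
#' @param k_mad QC MAD multiplier.
#' @param epsilon_bits cluster-selection entropy threshold.
#' @param k_neighbors graph neighborhood size shared by SNN, diffusion and
#'   velocity kernels.
#' @param k_max largest cluster count swept.
#' @param n_var_genes variable genes used for PCA and anchors.
#' @param n_floods flood repetitions for pseudotime.
#' @param n_walks Monte-Carlo walks per cell (oracle stage, optional).
#' @param driver_threshold |rho| cutoff for driver classification.
#' @param terminal_frac fraction of each fate population (latest cells
#'   first) declared terminal; 1 makes the whole population absorbing,
#'   the cluster-label terminal-state convention.
#' @param k_velocity neighborhood size of the velocity transition graph.
#' @param kernel_scale softmax temperature of the velocity kernel.
#' @param alpha significance level used by downstream counting.
#' @param window_nt TSS window half-width.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1, k_mad = 3,
                            epsilon_bits = 0.2, k_neighbors = 15,
                            k_max = 8, n_var_genes = 2000, n_floods = 50,
                            n_walks = 0, driver_threshold = 0.25,
                            terminal_frac = 1, k_velocity = 60,
                            kernel_scale = 0.25, alpha = 0.05,
                            window_nt = 250) {
  cfg <- as.list(environment())
  cfg$sim$seed <- seed
  # per-stage seeds, all < 2^31, derived deterministically
  cfg$stage_seeds <- list(
    simulate = seed,
    subsample = seed + 101L,
    cellcycle = seed + 211L,
    cluster = seed + 307L,
    pseudotime = seed + 401L,
    walks = seed + 503L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration as YAML
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{write_pipeline_config}: the path; \code{read_pipeline_config}:
#'   the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  x <- rapply(unclass(config), how = "replace", function(v) v)
  x$sim <- unclass(x$sim)
  x$sim$populations <- as.list(x$sim$populations)
  yaml::write_yaml(x, path)
  path
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$populations <- as.data.frame(x$sim$populations,
                                     stringsAsFactors = FALSE)
  sim <- x$sim
  class(sim) <- "sim_config"
  validate_sim_config(sim)
  x$sim <- sim
  class(x) <- "pipeline_config"
  x
}

#' Run the full simulated study end to end
#'
#' Simulate -> inject artifacts -> QC -> depth equalization ->
#' normalization -> wild-type clustering with entropy-based K selection ->
#' cross-genotype projection (forward and reverse) -> genotype DGEA ->
#' composition tests -> flood pseudotime with KS comparison -> velocity
#' fate probabilities -> driver classification and branching signature.
#' Every stage output is hashed into the run manifest; identical configs
#' reproduce identical hashes for all stages.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages character vector of stage names to run (dependencies are
#'   always satisfied in order); default all.
#' @param verbose print one line per stage.
#' @return list of class \code{pipeline_run}: stage outputs plus
#'   \code{manifest} (data.frame stage, hash, seconds).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "qc", "normalize",
                                    "cluster", "project", "dgea",
                                    "composition", "pseudotime", "fate"),
                         verbose = FALSE) {
  out <- list(); manifest <- list()
  note <- function(stage, value, secs) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, hash = rlang::hash(value), seconds = round(secs, 2))
    if (verbose) message(sprintf("[%s] %.1fs", stage, secs))
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[3]
    value <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           "\nreproduce with run_pipeline(config, stages = '", stage, "')",
           call. = FALSE))
    note(stage, value, proc.time()[3] - t0)
    value
  }

  sim <- run_stage("simulate", function() {
    s <- simulate_branching_lineage(config$sim)
    inject_qc_artifacts(s, config$sim)
  })
  out$sim <- sim

  if (!any(c("qc", "normalize", "cluster", "project", "dgea", "composition",
             "pseudotime", "fate") %in% stages))
    return(finish_run(out, manifest))

  qc <- run_stage("qc", function() {
    metrics <- compute_cell_qc(sim$cm)
    flt <- mad_filter(metrics, qc_thresholds(k_mad = config$k_mad))
    kept <- subset_cells(sim$cm, flt$keep)
    kept <- subsample_depth(kept, seed = config$stage_seeds$subsample)
    list(metrics = metrics, filter = flt, cm = kept)
  })
  out$qc <- qc
  cm <- qc$cm

  norm <- run_stage("normalize", function() {
    logmat <- normalize_log(cm)
    pearson <- normalize_pearson(cm)
    vg <- variable_genes(logmat, n_top = min(config$n_var_genes, nrow(logmat)))
    list(logmat = logmat, pearson = pearson, var_genes = vg)
  })
  out$norm <- norm

  wt <- cm$cell_meta$genotype == "wt"
  mut <- !wt

  clus <- run_stage("cluster", function() {
    pcs <- select_pcs(norm$pearson[, wt, drop = FALSE], genes = norm$var_genes)
    sweep_res <- suppressWarnings(
      cluster_sweep(pcs, k_neighbors = config$k_neighbors,
                    k_max = config$k_max,
                    seed = config$stage_seeds$cluster, strict = FALSE))
    tree <- suppressWarnings(build_cluster_tree(sweep_res$labelings))
    sel <- select_cluster_number(tree, config$epsilon_bits)
    list(pcs = pcs, tree = tree, k = sel$k, labels = sel$labels,
         curve = sel$curve)
  })
  out$cluster <- clus

  proj <- run_stage("project", function() {
    fwd_anchors <- find_anchors(norm$logmat[, wt, drop = FALSE],
                                norm$logmat[, mut, drop = FALSE],
                                genes = norm$var_genes)
    fwd <- transfer_labels(fwd_anchors, clus$labels)
    # reverse: cluster the mutant independently, project wt onto it
    pcs_m <- select_pcs(norm$pearson[, mut, drop = FALSE],
                        genes = norm$var_genes)
    sweep_m <- suppressWarnings(
      cluster_sweep(pcs_m, k_neighbors = config$k_neighbors,
                    k_max = config$k_max,
                    seed = config$stage_seeds$cluster, strict = FALSE))
    sel_m <- select_cluster_number(
      suppressWarnings(build_cluster_tree(sweep_m$labelings)),
      config$epsilon_bits)
    rev_anchors <- find_anchors(norm$logmat[, mut, drop = FALSE],
                                norm$logmat[, wt, drop = FALSE],
                                genes = norm$var_genes)
    rev <- transfer_labels(rev_anchors, sel_m$labels)
    conc <- reverse_projection_check(clus$labels, fwd$label,
                                     sel_m$labels, rev$label)
    list(forward = fwd, reverse = rev, mut_labels = sel_m$labels,
         concordance = conc)
  })
  out$project <- proj

  dg <- run_stage("dgea", function() {
    mann_whitney_dgea(norm$logmat, which(mut), which(wt))
  })
  out$dgea <- dg

  comp <- run_stage("composition", function() {
    labels <- character(ncol(cm$counts))
    labels[wt] <- as.character(clus$labels)
    labels[mut] <- as.character(proj$forward$label)
    composition_test(labels, cm$cell_meta$sample, cm$cell_meta$genotype)
  })
  out$composition <- comp

  pt <- run_stage("pseudotime", function() {
    pcs_all <- select_pcs(norm$pearson, genes = norm$var_genes)
    T_ <- diffusion_transitions(pcs_all$scores,
                                k_neighbors = config$k_neighbors)
    roots <- order(cm$cell_meta$latent_time)[seq_len(20)]
    res <- flood_pseudotime(T_, roots, n_floods = config$n_floods,
                            seed = config$stage_seeds$pseudotime)
    ks <- compare_pseudotime(res$pseudotime[wt], res$pseudotime[mut])
    list(result = res, ks = ks)
  })
  out$pseudotime <- pt

  fate <- run_stage("fate", function() {
    # velocity graphs are genotype-specific: fate bias is a property of
    # each genotype's own manifold, and pooling would average it away
    fp <- matrix(NA_real_, ncol(cm$counts), 2,
                 dimnames = list(cm$cell_meta$barcode, c("A", "B")))
    term <- rep(NA_character_, ncol(cm$counts))
    for (gt in unique(cm$cell_meta$genotype)) {
      gi <- which(cm$cell_meta$genotype == gt)
      res <- genotype_fate(cm, gi, config)
      fp[gi, colnames(res$fate_probs)] <- res$fate_probs
      term[gi] <- res$terminal
    }
    fp[is.na(fp)] <- 0
    # each fate's drivers are computed over its own lineage subset
    # (progenitors plus that branch); over the pooled branches the two
    # fate probabilities are complementary and the classes degenerate
    wt_a <- which(cm$cell_meta$genotype == "wt" &
                    cm$cell_meta$branch %in% c("pre", "A"))
    wt_b <- which(cm$cell_meta$genotype == "wt" &
                    cm$cell_meta$branch %in% c("pre", "B"))
    dr_a <- lineage_drivers(fp, norm$logmat, "A", wt_a,
                            threshold = config$driver_threshold)
    dr_b <- lineage_drivers(fp, norm$logmat, "B", wt_b,
                            threshold = config$driver_threshold)
    sig <- branching_signature(dr_a, dr_b)
    list(fate_probs = fp, drivers_a = dr_a, drivers_b = dr_b,
         signature = sig, terminal = term)
  })
  out$fate <- fate

  finish_run(out, manifest)
}

# velocity -> transition -> absorption for one genotype's cells; terminal
# states are the declared fate populations (their latest terminal_frac
# cells; 1 = the whole population, the cluster-label convention)
genotype_fate <- function(cm, cells, config) {
  sub <- subset_cells(cm, cells)
  vm <- estimate_velocity(sub$spliced, sub$unspliced,
                          k_smooth = config$k_neighbors)
  T_ <- velocity_transition_matrix(vm,
                                   k_neighbors = min(config$k_velocity,
                                                     ncol(sub$counts) - 1),
                                   kernel_scale = config$kernel_scale)
  lt <- sub$cell_meta$latent_time
  term <- rep(NA_character_, ncol(sub$counts))
  for (br in c("A", "B")) {
    bi <- sub$cell_meta$branch == br
    if (any(bi)) {
      thr <- stats::quantile(lt[bi], 1 - config$terminal_frac)
      term[bi & lt >= thr] <- br
    }
  }
  fp <- absorption_probabilities(T_, term)
  list(fate_probs = fp, terminal = term, model = vm, transition = T_)
}

#' Fate-bias recovery study
#'
#' The pipeline's genotype comparison of fate probabilities: for each
#' genotype, disjoint cell subsamples are drawn, an RNA-velocity-directed
#' transition graph is built per subsample, the declared fate populations
#' are made absorbing, and the mean fate-A absorption probability of
#' pre-branch (progenitor) cells is averaged over subsamples. The
#' relative reduction (wt - mut) / wt estimates the generative branch
#' bias difference.
#'
#' @param sim a \code{sim_output} from
#'   \code{\link{simulate_branching_lineage}}.
#' @param n_subsample cells per velocity graph (default 1750).
#' @param n_replicates disjoint subsamples per genotype (default 3).
#' @param k_smooth,k_neighbors,kernel_scale velocity-graph parameters.
#' @param seed RNG seed for the subsampling.
#' @return list: \code{mean_fate_a} named per genotype, \code{relative_reduction},
#'   \code{per_replicate} data.frame.
#' @export
fate_bias_study <- function(sim, n_subsample = 1750, n_replicates = 3,
                            k_smooth = 15, k_neighbors = 60,
                            kernel_scale = 0.25, seed = 1) {
  cm <- sim$cm
  set.seed(seed)
  rows <- list()
  m <- c()
  for (gt in c("wt", "mut")) {
    avail <- which(cm$cell_meta$genotype == gt &
                     cm$cell_meta$artifact == "none")
    n_use <- min(n_subsample * n_replicates, length(avail))
    pool <- sample(avail, n_use)
    per <- floor(n_use / n_replicates)
    vals <- c()
    for (rep in seq_len(n_replicates)) {
      gi <- sort(pool[((rep - 1) * per + 1):(rep * per)])
      sub <- subset_cells(cm, gi)
      vm <- estimate_velocity(sub$spliced, sub$unspliced,
                              k_smooth = k_smooth)
      T_ <- velocity_transition_matrix(
        vm, k_neighbors = min(k_neighbors, per - 1),
        kernel_scale = kernel_scale)
      brv <- sub$cell_meta$branch
      fp <- absorption_probabilities(
        T_, ifelse(brv %in% c("A", "B"), brv, NA))
      vals <- c(vals, mean(fp[brv == "pre", "A"]))
      rows[[length(rows) + 1]] <- data.frame(genotype = gt, replicate = rep,
                                             mean_fate_a = vals[rep])
    }
    m[gt] <- mean(vals)
  }
  list(mean_fate_a = m,
       relative_reduction = (m[["wt"]] - m[["mut"]]) / m[["wt"]],
       per_replicate = do.call(rbind, rows))
}

finish_run <- function(out, manifest) {
  out$manifest <- do.call(rbind, manifest)
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run with stages:\n")
  print(x$manifest[, c("stage", "hash", "seconds")], row.names = FALSE)
  invisible(x)
}
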