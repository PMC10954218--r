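#' PCA with component selection by the 2-MAD rule on explained variance
#'
#' Runs exact PCA on the variable-gene submatrix (centered per gene;
#' computed by eigendecomposition of the smaller Gram matrix) and keeps the
#' components whose explained variance exceeds median + 2 x MAD of the
#' full explained-variance spectrum. If no component qualifies the top
#' component is kept with a warning.
#'
#' @param X genes x cells normalized matrix.
#' @param genes gene names (or indices) to use; default all.
#' @param k_mad MAD multiplier on the spectrum (default 2).
#' @param max_pcs cap on the number of computed components.
#' @return list of class \code{pc_selection}: \code{scores} (cells x
#'   n_selected), \code{loadings}, \code{explained_variance} (full
#'   spectrum, non-increasing), \code{n_selected}.
#' @export
select_pcs <- function(X, genes = NULL, k_mad = 2, max_pcs = 50) {
  if (!is.null(genes)) X <- X[genes, , drop = FALSE]
  if (nrow(X) < 2 || ncol(X) < 3)
    stop("need at least 2 variable genes and 3 cells")
  Xc <- X - rowMeans(X)
  if (all(abs(Xc) < 1e-12)) stop("constant matrix: no principal components")
  n <- ncol(Xc); G <- nrow(Xc)
  if (G <= n) {                       # gene-space Gram
    C <- tcrossprod(Xc) / (n - 1)
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    loadings <- e$vectors
    scores <- crossprod(Xc, loadings)
  } else {                            # cell-space Gram
    C <- crossprod(Xc) / (n - 1)
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    nz <- ev > 1e-12
    scores <- e$vectors %*% diag(sqrt(ev * (n - 1)), length(ev))
    loadings <- Xc %*% e$vectors
    loadings[, nz] <- sweep(loadings[, nz, drop = FALSE], 2,
                            sqrt(ev[nz] * (n - 1)), "/")
  }
  spectrum <- ev[seq_len(min(length(ev), max(max_pcs, sum(ev > 1e-12))))]
  med <- stats::median(ev)
  madv <- stats::median(abs(ev - med))
  thr <- med + k_mad * madv
  n_sel <- sum(ev > thr & seq_along(ev) <= max_pcs)
  if (n_sel == 0) {
    warning("no component exceeds the MAD threshold; keeping the top one")
    n_sel <- 1
  }
  structure(list(scores = scores[, seq_len(n_sel), drop = FALSE],
                 loadings = loadings[, seq_len(n_sel), drop = FALSE],
                 explained_variance = ev,
                 n_selected = n_sel),
            class = "pc_selection")
}

louvain_at <- function(g, resolution, seed) {
  # derive the RNG state from (seed, resolution): the same resolution
  # always reproduces its labeling, while different resolutions explore
  # independent optimizer paths - splits that survive across resolutions
  # are then genuinely stable, not artifacts of a shared RNG stream
  set.seed((seed + round(resolution * 1e4)) %% .Machine$integer.max)
  igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
}

#' Louvain clustering across a resolution sweep
#'
#' Builds the shared-nearest-neighbor graph once, then searches resolutions
#' (coarse grid plus bisection) for labelings achieving each cluster count
#' in \code{2..k_max}. Louvain is seeded, so the whole sweep is
#' reproducible.
#'
#' @param pcs a \code{\link{select_pcs}} result (or a cells x dims matrix).
#' @param k_neighbors kNN size for the SNN graph.
#' @param k_max largest cluster count sought.
#' @param seed RNG seed (same seed before every Louvain call).
#' @param max_resolution upper end of the resolution search.
#' @param prune SNN pruning threshold.
#' @param strict error when \code{k_max} cannot be reached (default);
#'   \code{FALSE} downgrades to a warning and returns the achievable
#'   range (Louvain can jump over particular cluster counts).
#' @return list of class \code{cluster_sweep}: \code{labelings} (named
#'   list, one integer labeling per achieved cluster count),
#'   \code{resolutions} used, \code{graph} (the SNN igraph).
#' @export
cluster_sweep <- function(pcs, k_neighbors = 15, k_max = 10, seed = 1,
                          max_resolution = 10, prune = 1 / 15,
                          strict = TRUE) {
  emb <- if (inherits(pcs, "pc_selection")) pcs$scores else as.matrix(pcs)
  if (k_neighbors >= nrow(emb)) stop("k_neighbors must be < n_cells")
  knn <- knn_index(emb, k_neighbors)
  g <- snn_graph(knn, prune = prune)
  labelings <- list(); resolutions <- c()
  record <- function(memb, res) {
    k <- length(unique(memb))
    key <- as.character(k)
    if (k >= 2 && k <= k_max && is.null(labelings[[key]])) {
      labelings[[key]] <<- as.integer(memb)
      resolutions[key] <<- res
    }
    k
  }
  grid <- sort(unique(c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1, 1.05, 1.1, 1.2,
                        1.4, 1.7, 2, 3, 4, 6, max_resolution)))
  ks <- vapply(grid, function(r) record(louvain_at(g, r, seed), r), numeric(1))
  # bisect between grid points to fill in missing cluster counts
  for (pass in 1:3) {
    missing <- setdiff(2:k_max, as.integer(names(labelings)))
    if (!length(missing)) break
    pts <- sort(stats::setNames(resolutions, NULL))
    pts <- sort(unique(c(grid, pts)))
    for (m in missing) {
      have <- as.integer(names(labelings))
      lo_k <- max(have[have < m], 1); hi_k <- min(have[have > m], Inf)
      lo <- if (lo_k > 1) resolutions[[as.character(lo_k)]] else min(grid)
      hi <- if (is.finite(hi_k)) resolutions[[as.character(hi_k)]] else max_resolution
      for (it in 1:12) {
        mid <- (lo + hi) / 2
        k <- record(louvain_at(g, mid, seed), mid)
        if (k == m) break
        if (k < m) lo <- mid else hi <- mid
      }
    }
  }
  if (!as.character(k_max) %in% names(labelings)) {
    ach <- sort(as.integer(names(labelings)))
    msg <- paste0("k_max = ", k_max, " unreachable at resolution <= ",
                  max_resolution, "; achievable cluster counts: ",
                  paste(ach, collapse = ", "))
    if (strict || length(ach) < 1) stop(msg) else warning(msg)
  }
  ord <- order(as.integer(names(labelings)))
  structure(list(labelings = labelings[ord],
                 resolutions = resolutions[names(labelings)[ord]],
                 graph = g),
            class = "cluster_sweep")
}

#' Clustering tree with per-node Shannon entropy
#'
#' Links clusterings at consecutive cluster counts by the flow of cells:
#' each child node's edge proportions record what fraction of its cells
#' came from each parent cluster at the previous level, and its entropy
#' H = -sum p log2 p (bits) measures split stability (H = 0 iff a single
#' parent).
#'
#' @param labelings named list of integer labelings, names = cluster
#'   counts, as from \code{\link{cluster_sweep}}.
#' @return list of class \code{cluster_tree}: \code{edges}
#'   data.frame(level_parent, level_child, parent, child, proportion),
#'   \code{node_entropy} data.frame(level, node, H_bits), \code{levels}
#'   the labelings.
#' @export
build_cluster_tree <- function(labelings) {
  ks <- as.integer(names(labelings))
  if (is.unsorted(ks)) {
    labelings <- labelings[order(ks)]; ks <- sort(ks)
  }
  if (any(diff(ks) != 1))
    warning("cluster counts are not consecutive: ",
            paste(ks, collapse = ", "))
  edges <- list(); ent <- list()
  # the coarsest level descends from the trivial one-cluster root: H = 0
  k0 <- ks[1]
  ent[[1]] <- data.frame(level = k0, node = sort(unique(labelings[[1]])),
                         H_bits = 0)
  for (i in seq_len(length(ks) - 1)) {
    par <- labelings[[i]]; chi <- labelings[[i + 1]]
    for (cnode in sort(unique(chi))) {
      in_child <- chi == cnode
      tab <- table(par[in_child])
      p <- as.numeric(tab) / sum(tab)
      edges[[length(edges) + 1]] <- data.frame(
        level_parent = ks[i], level_child = ks[i + 1],
        parent = as.integer(names(tab)), child = cnode, proportion = p)
      ent[[length(ent) + 1]] <- data.frame(
        level = ks[i + 1], node = cnode,
        H_bits = -sum(p * log2(p)))
    }
  }
  structure(list(edges = do.call(rbind, edges),
                 node_entropy = do.call(rbind, ent),
                 levels = labelings),
            class = "cluster_tree")
}

#' Select the cluster number from a clustering tree
#'
#' Maximizes the cluster count while keeping the Shannon entropy of the
#' tree low. Two statistics and two rules are available:
#' \itemize{
#'   \item \code{statistic}: "mean" scores a level by its mean per-node
#'     entropy; "total" by the sum over nodes (a single even two-parent
#'     mix contributes one full bit, so overclustering of one population
#'     is not diluted by many clean nodes).
#'   \item \code{rule}: "threshold" returns the largest K whose level
#'     score is at most \code{epsilon_bits}. "stable_chain" additionally
#'     requires the next level (K + 1) to be clean: a clustering only
#'     counts as stable when refining it one step further does not shuffle
#'     cells across its boundaries. Because a single split always nests
#'     cleanly into its parent (its children inherit from one parent
#'     each), the first overclustered level is invisible to its own score;
#'     the lookahead is what detects it.
#' }
#' If no level qualifies, the level with minimal score is returned.
#'
#' @param tree a \code{\link{build_cluster_tree}} result.
#' @param epsilon_bits stability threshold in bits (default 0.2).
#' @param statistic "mean" (default) or "total" per-level entropy.
#' @param rule "threshold" (default) or "stable_chain".
#' @return list: \code{k} chosen cluster count, \code{curve}
#'   data.frame(level, entropy_bits), \code{labels} the chosen labeling.
#' @export
select_cluster_number <- function(tree, epsilon_bits = 0.2,
                                  statistic = c("mean", "total"),
                                  rule = c("threshold", "stable_chain")) {
  statistic <- match.arg(statistic)
  rule <- match.arg(rule)
  curve <- entropy_curve(tree, statistic)
  k <- select_k_from_curve(curve, epsilon_bits, rule)
  labels <- tree$levels[[as.character(k)]]
  list(k = k, curve = curve, labels = labels)
}

entropy_curve <- function(tree, statistic = "mean") {
  ne <- tree$node_entropy
  f <- if (statistic == "mean") mean else sum
  curve <- stats::aggregate(H_bits ~ level, data = ne, FUN = f)
  names(curve) <- c("level", "entropy_bits")
  curve
}

select_k_from_curve <- function(curve, epsilon_bits, rule) {
  lv <- curve$level
  clean <- curve$entropy_bits <= epsilon_bits
  ok <- if (rule == "threshold") clean
        else vapply(seq_along(lv), function(i) {
          j <- which(lv == lv[i] + 1)
          clean[i] && (lv[i] == max(lv) || !length(j) || clean[j])
        }, logical(1))
  if (any(ok)) max(lv[ok]) else lv[which.min(curve$entropy_bits)]
}

#' Consensus cluster-number selection over replicate sweeps
#'
#' Runs the resolution sweep several times with independent seeds,
#' averages the per-level entropy curves, and applies the selection rule
#' to the consensus curve; replicate averaging removes the chance that a
#' single optimizer run happens to refine an overclustered level cleanly.
#'
#' @param pcs a \code{\link{select_pcs}} result (or embedding matrix).
#' @param k_neighbors,k_max,max_resolution,prune as
#'   \code{\link{cluster_sweep}}.
#' @param n_replicates sweep replicates (default 3).
#' @param seed base seed; replicate r uses seed + 1000 * (r - 1).
#' @param epsilon_bits,statistic,rule as
#'   \code{\link{select_cluster_number}} (defaults here: total-entropy
#'   stable-chain, epsilon 0.4 bits).
#' @return list: \code{k}, \code{curve} (consensus), \code{labels}
#'   (first replicate's labeling at k, if achieved), \code{sweeps}.
#' @export
consensus_cluster_number <- function(pcs, k_neighbors = 15, k_max = 10,
                                     n_replicates = 3, seed = 1,
                                     epsilon_bits = 0.4,
                                     statistic = "total",
                                     rule = "stable_chain",
                                     max_resolution = 10, prune = 1 / 15) {
  sweeps <- list(); curves <- list()
  for (r in seq_len(n_replicates)) {
    sw <- suppressWarnings(
      cluster_sweep(pcs, k_neighbors = k_neighbors, k_max = k_max,
                    seed = seed + 1000L * (r - 1L),
                    max_resolution = max_resolution, prune = prune,
                    strict = FALSE))
    tree <- suppressWarnings(build_cluster_tree(sw$labelings))
    sweeps[[r]] <- sw
    curves[[r]] <- entropy_curve(tree, statistic)
  }
  all_lv <- sort(unique(unlist(lapply(curves, `[[`, "level"))))
  avg <- vapply(all_lv, function(K) {
    mean(unlist(lapply(curves, function(cv)
      cv$entropy_bits[cv$level == K])), na.rm = TRUE)
  }, numeric(1))
  curve <- data.frame(level = all_lv, entropy_bits = avg)
  k <- select_k_from_curve(curve, epsilon_bits, rule)
  labels <- NULL
  for (sw in sweeps)
    if (is.null(labels) && !is.null(sw$labelings[[as.character(k)]]))
      labels <- sw$labelings[[as.character(k)]]
  list(k = k, curve = curve, labels = labels, sweeps = sweeps)
}
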