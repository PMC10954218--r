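#' Diffusion-map transition probabilities on a kNN graph
#'
#' Builds a symmetric Gaussian kernel on kNN distances (union of neighbor
#' sets, self-transitions excluded), applies density normalization
#' (dividing by the product of row sums, removing sampling-density bias),
#' and row-normalizes to a stochastic matrix.
#'
#' @param embedding cells x dims matrix.
#' @param k_neighbors kNN size.
#' @param bandwidth Gaussian kernel bandwidth; default the median kNN
#'   distance.
#' @return sparse row-stochastic \code{dgCMatrix}; errors on a
#'   disconnected graph, listing component sizes.
#' @export
diffusion_transitions <- function(embedding, k_neighbors = 15,
                                  bandwidth = NULL) {
  knn <- knn_index(as.matrix(embedding), k_neighbors)
  n <- nrow(knn$index)
  if (is.null(bandwidth)) bandwidth <- stats::median(knn$dist)
  if (bandwidth <= 0) bandwidth <- 1
  i <- rep(seq_len(n), k_neighbors)
  j <- as.vector(knn$index)
  w <- exp(-as.vector(knn$dist)^2 / bandwidth^2)
  W2 <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  W <- pmax_sparse(W2, Matrix::t(W2))   # symmetric: union of neighbor sets
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("kNN graph is disconnected: ", comp$no, " components of sizes ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  q <- Matrix::rowSums(W)
  Wd <- Matrix::Diagonal(x = 1 / q) %*% W %*% Matrix::Diagonal(x = 1 / q)
  rs <- Matrix::rowSums(Wd)
  T_ <- Matrix::Diagonal(x = 1 / rs) %*% Wd
  methods::as(T_, "CsparseMatrix")
}

# elementwise max of two sparse matrices with identical dims
pmax_sparse <- function(A, B) {
  D <- (A + B + abs(A - B)) / 2
  Matrix::drop0(D)
}

#' Probabilistic graph-flood pseudotime
#'
#' From an assigned set of root cells, performs seeded probabilistic
#' breadth-first expansions over the transition matrix: at each iteration
#' every unvisited cell becomes visited with probability min(1, sum of
#' incoming transition mass from already-visited cells), until the whole
#' graph is visited. Pseudotime is each cell's average first-visit
#' iteration over \code{n_floods} repetitions, min-max normalized to
#' [0, 1]; root cells have pseudotime exactly 0.
#'
#' @param T_ row-stochastic transition matrix (cells x cells).
#' @param roots indices of the root cells.
#' @param n_floods number of flood repetitions (default 100).
#' @param seed RNG seed.
#' @return list of class \code{pseudotime_result}: \code{pseudotime}
#'   (normalized), \code{mean_iteration}, \code{sd_iteration},
#'   \code{n_floods}.
#' @export
flood_pseudotime <- function(T_, roots, n_floods = 100, seed = 1) {
  n <- nrow(T_)
  if (!length(roots)) stop("root set is empty")
  set.seed(seed)
  max_iter <- 10 * n
  iter_sum <- numeric(n); iter_sq <- numeric(n)
  for (f in seq_len(n_floods)) {
    visited <- logical(n)
    visited[roots] <- TRUE
    it_of <- numeric(n)
    it <- 0
    while (!all(visited)) {
      it <- it + 1
      if (it > max_iter)
        stop("flood did not cover the graph within ", max_iter, " iterations")
      mass <- as.numeric(T_ %*% visited)
      p <- pmin(1, mass)
      newly <- !visited & stats::runif(n) < p
      if (!any(newly)) next
      it_of[newly] <- it
      visited[newly] <- TRUE
    }
    iter_sum <- iter_sum + it_of
    iter_sq <- iter_sq + it_of^2
  }
  m <- iter_sum / n_floods
  v <- pmax(iter_sq / n_floods - m^2, 0)
  rng <- range(m)
  pt <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  structure(list(pseudotime = pt, mean_iteration = m,
                 sd_iteration = sqrt(v), n_floods = n_floods),
            class = "pseudotime_result")
}

#' Two-sample Kolmogorov-Smirnov comparison of pseudotime distributions
#'
#' @param pt_a,pt_b pseudotime vectors (each >= 10 cells).
#' @param labels_a,labels_b optional per-cell group labels; when supplied,
#'   per-group comparisons are returned as well.
#' @return data.frame(group, n_a, n_b, D, p); group "all" is the pooled
#'   comparison.
#' @export
compare_pseudotime <- function(pt_a, pt_b, labels_a = NULL, labels_b = NULL) {
  if (length(pt_a) < 10 || length(pt_b) < 10)
    stop("both samples need >= 10 cells")
  run <- function(a, b, name) {
    ks <- suppressWarnings(stats::ks.test(a, b))
    data.frame(group = name, n_a = length(a), n_b = length(b),
               D = unname(ks$statistic), p = ks$p.value)
  }
  out <- run(pt_a, pt_b, "all")
  if (!is.null(labels_a) && !is.null(labels_b)) {
    for (grp in intersect(unique(labels_a), unique(labels_b))) {
      a <- pt_a[labels_a == grp]; b <- pt_b[labels_b == grp]
      if (length(a) >= 10 && length(b) >= 10)
        out <- rbind(out, run(a, b, grp))
    }
  }
  out
}

#' Pick root cells by marker expression
#'
#' Roots for the flood are the cells with the highest mean expression of a
#' root-marker gene set (e.g. progenitor markers).
#'
#' @param logmat genes x cells log-normalized expression.
#' @param markers root marker genes.
#' @param n_roots number of root cells.
#' @return integer cell indices.
#' @export
root_cells_by_markers <- function(logmat, markers, n_roots = 20) {
  markers <- intersect(markers, rownames(logmat))
  if (!length(markers)) stop("no root marker present in the matrix")
  sc <- colMeans(logmat[markers, , drop = FALSE])
  order(sc, decreasing = TRUE)[seq_len(min(n_roots, ncol(logmat)))]
}
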