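#' Exact k-nearest neighbors by blocked Euclidean distance
#'
#' @param X cells x dims embedding matrix.
#' @param k number of neighbors (excluding self).
#' @param block block size for the distance computation.
#' @return list(index, dist): cells x k matrices of neighbor indices and
#'   distances, nearest first.
#' @export
knn_index <- function(X, k, block = 512) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    D2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
    D2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
    for (j in seq_along(rows)) {
      o <- order(D2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(D2[j, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

#' Shared-nearest-neighbor graph with Jaccard edge weights
#'
#' Builds the kNN adjacency (each cell's neighbor set includes itself),
#' weights each cell pair by the Jaccard overlap of their neighbor sets,
#' and prunes weights below \code{prune}.
#'
#' @param knn result of \code{\link{knn_index}}.
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return an undirected weighted \code{igraph} graph.
#' @export
snn_graph <- function(knn, prune = 1 / 15) {
  n <- nrow(knn$index)
  k <- ncol(knn$index) + 1   # neighbor sets include self
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k),
    j = c(as.vector(knn$index), seq_len(n)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac <- Matrix::drop0(jac * (jac >= prune))
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}
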