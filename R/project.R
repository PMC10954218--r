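#' Find cross-dataset anchors by mutual nearest neighbors in a joint PCA
#'
#' Scales the shared variable genes within each dataset, runs one PCA on
#' the concatenated cells, and pairs reference and query cells that are
#' mutual k-nearest neighbors across datasets. Each anchor is scored by
#' the Jaccard overlap of the two cells' neighborhoods in the joint
#' embedding (in [0, 1]).
#'
#' @param ref,query genes x cells log-normalized matrices on a shared gene
#'   space.
#' @param genes shared variable genes to use.
#' @param k_anchor cross-dataset neighbors searched for mutual pairs.
#' @param k_score neighborhood size for the Jaccard anchor score.
#' @param n_pcs joint-PCA dimensionality.
#' @return list of class \code{anchor_set}: \code{pairs}
#'   data.frame(ref_cell, query_cell, score), plus the joint embeddings
#'   \code{ref_embedding}, \code{query_embedding}.
#' @export
find_anchors <- function(ref, query, genes = NULL, k_anchor = 5,
                         k_score = 30, n_pcs = 30) {
  if (is.null(genes)) genes <- intersect(rownames(ref), rownames(query))
  genes <- intersect(genes, intersect(rownames(ref), rownames(query)))
  if (length(genes) < 2) stop("need at least 2 shared genes")
  # standardize both datasets by the reference per-gene statistics:
  # per-dataset centering or scaling would shift a query with different
  # population composition onto the reference centroid (or inflate genes
  # whose variation the query does not sample)
  mu_ref <- rowMeans(ref[genes, , drop = FALSE])
  sd_ref <- apply(ref[genes, , drop = FALSE], 1, stats::sd)
  sd_ref[sd_ref == 0] <- 1
  R <- (ref[genes, , drop = FALSE] - mu_ref) / sd_ref
  Q <- (query[genes, , drop = FALSE] - mu_ref) / sd_ref
  nR <- ncol(R); nQ <- ncol(Q)
  if (nR < k_anchor || nQ < k_anchor)
    stop("need at least k_anchor cells in each dataset")
  joint <- cbind(R, Q)
  pcs <- select_pcs(joint, k_mad = 0, max_pcs = n_pcs)
  emb <- pcs$scores[, seq_len(min(n_pcs, ncol(pcs$scores))), drop = FALSE]
  is_ref <- c(rep(TRUE, nR), rep(FALSE, nQ))
  # cross-dataset kNN: nearest ref for each query and vice versa
  cross_nn <- function(A, B, k) {   # for each row of A, k nearest rows of B
    sqA <- rowSums(A^2); sqB <- rowSums(B^2)
    D2 <- outer(sqA, sqB, "+") - 2 * A %*% t(B)
    t(apply(D2, 1, function(d) order(d)[seq_len(k)]))
  }
  embR <- emb[is_ref, , drop = FALSE]; embQ <- emb[!is_ref, , drop = FALSE]
  nnQ_of_R <- cross_nn(embR, embQ, min(k_anchor, nQ))
  nnR_of_Q <- cross_nn(embQ, embR, min(k_anchor, nR))
  pairs <- list()
  for (r in seq_len(nR)) for (q in nnQ_of_R[r, ])
    if (r %in% nnR_of_Q[q, ]) pairs[[length(pairs) + 1]] <- c(r, q)
  if (!length(pairs))
    stop("no mutual-nearest-neighbor anchors found: datasets appear disjoint")
  pairs <- do.call(rbind, pairs)
  # score: Jaccard of k_score-neighborhoods in the joint space
  kk <- min(k_score, nR + nQ - 1)
  knn_all <- knn_index(emb, kk)
  nsets <- cbind(knn_all$index, seq_len(nR + nQ))
  score <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- nsets[pairs[i, 1], ]; b <- nsets[nR + pairs[i, 2], ]
    ov <- length(intersect(a, b))
    ov / (2 * (kk + 1) - ov)
  }, numeric(1))
  structure(list(pairs = data.frame(ref_cell = pairs[, 1],
                                    query_cell = pairs[, 2],
                                    score = score),
                 ref_embedding = embR, query_embedding = embQ,
                 ref_names = colnames(ref), query_names = colnames(query)),
            class = "anchor_set")
}

#' Transfer reference labels to query cells through anchors
#'
#' Each query cell takes the anchor-score-weighted majority label of its
#' anchors. Ties are broken by higher total anchor score, then by smaller
#' cluster index. Query cells with no anchor inherit the call of their
#' nearest anchored query neighbor in the joint embedding and are flagged
#' \code{imputed}; every query cell therefore receives exactly one label.
#'
#' @param anchors an \code{\link{find_anchors}} result.
#' @param ref_labels vector of reference cluster labels (one per reference
#'   cell).
#' @return data.frame(query_cell, label, score, imputed): \code{score} is
#'   the winning label's share of total anchor weight.
#' @export
transfer_labels <- function(anchors, ref_labels) {
  p <- anchors$pairs
  if (!nrow(p)) stop("anchor set is empty")
  nQ <- nrow(anchors$query_embedding)
  lab <- rep(NA_character_, nQ); sc <- rep(NA_real_, nQ)
  lev <- sort(unique(as.character(ref_labels)))
  for (q in unique(p$query_cell)) {
    rows <- p[p$query_cell == q, ]
    w <- tapply(rows$score, as.character(ref_labels[rows$ref_cell]), sum)
    top <- names(w)[w == max(w)]
    win <- if (length(top) == 1) top else top[order(match(top, lev))][1]
    lab[q] <- win
    tw <- sum(rows$score)
    sc[q] <- if (tw > 0) w[[win]] / tw else 1 / length(w)
  }
  imputed <- is.na(lab)
  if (any(imputed)) {
    anchored <- which(!imputed)
    for (q in which(imputed)) {
      d2 <- rowSums(sweep(anchors$query_embedding[anchored, , drop = FALSE],
                          2, anchors$query_embedding[q, ], "-")^2)
      nn <- anchored[which.min(d2)]
      lab[q] <- lab[nn]; sc[q] <- sc[nn]
    }
  }
  data.frame(query_cell = seq_len(nQ),
             barcode = anchors$query_names,
             label = lab, score = sc, imputed = imputed)
}

#' Forward vs reverse projection concordance
#'
#' The projection control: composition differences (mutant minus
#' wild-type) measured after forward projection (mutant cells onto
#' wild-type clusters) are compared against those measured after reverse
#' projection (wild-type cells onto independently derived mutant
#' clusters). Mutant clusters are matched to wild-type clusters by the
#' plurality forward label of their cells. Genuine composition shifts
#' agree in sign between the two directions; projection noise would not.
#'
#' @param wt_labels wild-type cells' own cluster labels.
#' @param mut_fwd_labels mutant cells' labels in wild-type cluster space
#'   (forward projection).
#' @param mut_labels mutant cells' own (independent) cluster labels.
#' @param wt_rev_labels wild-type cells' labels in mutant cluster space
#'   (reverse projection).
#' @return list: \code{table} data.frame(population, delta_forward,
#'   delta_reverse, sign_agree), \code{sign_agreement} fraction over
#'   populations with nonzero deltas, \code{delta_correlation} Pearson
#'   correlation of the two delta vectors.
#' @export
reverse_projection_check <- function(wt_labels, mut_fwd_labels,
                                     mut_labels, wt_rev_labels) {
  wt_labels <- as.character(wt_labels)
  mut_fwd_labels <- as.character(mut_fwd_labels)
  mut_labels <- as.character(mut_labels)
  wt_rev_labels <- as.character(wt_rev_labels)
  pops <- sort(unique(c(wt_labels, mut_fwd_labels)))
  prop <- function(x, lev) {
    tab <- table(factor(x, levels = lev))
    as.numeric(tab) / length(x)
  }
  delta_fwd <- prop(mut_fwd_labels, pops) - prop(wt_labels, pops)
  # match each mutant cluster to the wt cluster its cells mostly project to
  map <- vapply(sort(unique(mut_labels)), function(mc) {
    tab <- table(mut_fwd_labels[mut_labels == mc])
    names(tab)[which.max(tab)]
  }, character(1))
  mut_in_wt_space <- unname(map[mut_labels])
  wt_rev_in_wt_space <- unname(map[wt_rev_labels])
  delta_rev <- prop(mut_in_wt_space, pops) - prop(wt_rev_in_wt_space, pops)
  nz <- abs(delta_fwd) > 1e-12 | abs(delta_rev) > 1e-12
  agree <- sign(delta_fwd) == sign(delta_rev)
  list(table = data.frame(population = pops, delta_forward = delta_fwd,
                          delta_reverse = delta_rev, sign_agree = agree),
       sign_agreement = if (any(nz)) mean(agree[nz]) else 1,
       delta_correlation = if (sum(nz) > 1)
         stats::cor(delta_fwd[nz], delta_rev[nz]) else NA_real_)
}
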