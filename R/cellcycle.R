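#' Cell-cycle phase assignment from marker scores
#'
#' Scores each cell for S-phase and G2/M-phase marker expression as the
#' mean marker expression minus the mean of a size-matched control gene
#' set sampled from expression-matched bins (seeded). A cell is assigned
#' the higher-scoring phase when either score is positive; cells
#' expressing neither program are called G1.
#'
#' @param logmat genes x cells log-normalized expression.
#' @param s_genes,g2m_genes disjoint marker gene sets present in the
#'   matrix.
#' @param n_bins expression bins for control matching.
#' @param seed RNG seed for control sampling.
#' @return data.frame(barcode, s_score, g2m_score, phase).
#' @export
assign_cell_cycle <- function(logmat, s_genes, g2m_genes, n_bins = 25,
                              seed = 1) {
  s_genes <- intersect(s_genes, rownames(logmat))
  g2m_genes <- intersect(g2m_genes, rownames(logmat))
  if (!length(s_genes) || !length(g2m_genes))
    stop("both marker sets must be non-empty and present in the matrix")
  if (length(intersect(s_genes, g2m_genes)))
    stop("S and G2M marker sets overlap")
  set.seed(seed)
  mu <- rowMeans(logmat)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- as.integer(cut(mu, breaks = br, include.lowest = TRUE))
  names(bin) <- rownames(logmat)
  score <- function(markers) {
    ctrl <- unlist(lapply(markers, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], c(s_genes, g2m_genes))
      if (!length(pool)) pool <- setdiff(names(bin), c(s_genes, g2m_genes))
      pool[sample.int(length(pool), 1)]
    }))
    colMeans(logmat[markers, , drop = FALSE]) -
      colMeans(logmat[ctrl, , drop = FALSE])
  }
  s_score <- score(s_genes)
  g2m_score <- score(g2m_genes)
  phase <- ifelse(pmax(s_score, g2m_score) <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(barcode = colnames(logmat), s_score = s_score,
             g2m_score = g2m_score, phase = phase, row.names = NULL)
}
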