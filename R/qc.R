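#' Per-cell QC metrics
#'
#' Computes, from raw counts, the three filtering criteria: total
#' transcripts (\code{n_counts}), number of detected genes
#' (\code{n_genes}), and mitochondrial fraction (\code{pct_mito}, in
#' [0, 1]; defined as 0 for an empty cell, which the count criteria remove
#' anyway).
#'
#' @param cm a \code{\link{count_matrix}} whose gene metadata carries a
#'   logical \code{mito} column.
#' @return data.frame(barcode, n_counts, n_genes, pct_mito) plus any
#'   grouping columns (\code{sample}, \code{stage}) present in the cell
#'   metadata.
#' @export
compute_cell_qc <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!"mito" %in% names(cm$gene_meta))
    stop("gene metadata has no 'mito' flag column")
  mito <- cm$gene_meta$mito
  if (!any(mito)) warning("no gene is flagged mitochondrial; pct_mito will be 0")
  tot <- Matrix::colSums(cm$counts)
  mtot <- if (any(mito)) Matrix::colSums(cm$counts[mito, , drop = FALSE]) else 0
  out <- data.frame(
    barcode = cm$cell_meta$barcode,
    n_counts = as.numeric(tot),
    n_genes = as.numeric(Matrix::colSums(cm$counts > 0)),
    pct_mito = ifelse(tot > 0, as.numeric(mtot) / pmax(tot, 1), 0))
  for (col in intersect(c("sample", "stage", "genotype"), names(cm$cell_meta)))
    out[[col]] <- cm$cell_meta[[col]]
  out
}

#' MAD-filter thresholds
#'
#' @param k_mad multiplier on the median absolute deviation (default 3).
#' @param sidedness named character vector per metric, values in
#'   \{"upper","lower","both"\}. Mitochondrial fraction is filtered
#'   upper-side only; the two library-size metrics two-sided, so both empty
#'   droplets and doublets are caught.
#' @param mad_constant scale factor on the raw MAD (default 1.4826, the
#'   consistency constant making k MADs comparable to k standard
#'   deviations on Gaussian metrics, as in \code{stats::mad}; set 1 for
#'   the raw median absolute deviation).
#' @return list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(k_mad = 3,
                          sidedness = c(pct_mito = "upper",
                                        n_genes = "both",
                                        n_counts = "both"),
                          mad_constant = 1.4826) {
  stopifnot(k_mad > 0, mad_constant > 0,
            all(sidedness %in% c("upper", "lower", "both")))
  structure(list(k_mad = k_mad, sidedness = sidedness,
                 mad_constant = mad_constant),
            class = "qc_thresholds")
}

#' Remove outlier cells by the k-MAD rule, per stage group
#'
#' Within each stage group, a cell is removed when any configured metric
#' exceeds median +/- k * MAD on the metric's configured side, with
#' MAD = mad_constant * median(|x - median(x)|) (the Gaussian-consistent
#' scaling by default). When a metric's MAD is 0 the scale falls back to
#' IQR/1.349; when that is also 0, any value different from the median
#' counts as exceeding (otherwise no cell could ever be removed from
#' near-constant inputs).
#'
#' @param metrics data.frame from \code{\link{compute_cell_qc}}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param stage_group vector assigning each cell to a stage group (default:
#'   the \code{stage} column of \code{metrics}, else one group).
#' @return list: \code{keep} logical vector, \code{report} data.frame of
#'   removals per group and criterion, \code{bounds} the thresholds used
#'   (frozen from the first pass; the filter is idempotent on its output).
#' @export
mad_filter <- function(metrics, thresholds = qc_thresholds(),
                       stage_group = NULL) {
  if (is.null(stage_group))
    stage_group <- if ("stage" %in% names(metrics)) metrics$stage
                   else rep("all", nrow(metrics))
  mcols <- intersect(names(thresholds$sidedness), names(metrics))
  if (!length(mcols)) stop("no threshold metric present in `metrics`")
  keep <- rep(TRUE, nrow(metrics))
  report <- list(); bounds <- list()
  for (grp in unique(stage_group)) {
    gi <- which(stage_group == grp)
    if (length(gi) < 10)
      warning("stage group '", grp, "' has fewer than 10 cells")
    mads <- vapply(mcols, function(mc)
      stats::median(abs(metrics[[mc]][gi] - stats::median(metrics[[mc]][gi]))),
      numeric(1))
    if (all(mads == 0))
      warning("stage group '", grp,
              "' has zero MAD on every metric; using fallback scales")
    for (mc in mcols) {
      x <- metrics[[mc]][gi]
      med <- stats::median(x)
      scale <- thresholds$mad_constant * stats::median(abs(x - med))
      if (scale == 0) scale <- stats::IQR(x) / 1.349
      if (scale == 0) {
        bad <- x != med
        lo <- hi <- med
      } else {
        lo <- med - thresholds$k_mad * scale
        hi <- med + thresholds$k_mad * scale
        bad <- switch(thresholds$sidedness[[mc]],
                      upper = x > hi, lower = x < lo, both = x < lo | x > hi)
      }
      keep[gi][bad] <- FALSE
      report[[length(report) + 1]] <- data.frame(
        stage_group = grp, metric = mc, lower = lo, upper = hi,
        n_removed = sum(bad))
      bounds[[paste(grp, mc)]] <- c(lower = lo, upper = hi)
    }
  }
  list(keep = keep, report = do.call(rbind, report), bounds = bounds)
}

#' Equalize library depth across samples by binomial thinning
#'
#' Within each stage group, every sample's counts are thinned entrywise
#' with probability min_total/sample_total, so all libraries have the same
#' expected total as the shallowest one. Zeros stay zero; thinning is
#' deterministic under the seed.
#'
#' @param cm a \code{\link{count_matrix}} with a \code{sample} column.
#' @param seed RNG seed.
#' @param stage_group optional grouping vector (default the \code{stage}
#'   column).
#' @return the thinned \code{count_matrix} (all layers thinned with the
#'   same per-sample probability).
#' @export
subsample_depth <- function(cm, seed = 1, stage_group = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(stage_group))
    stage_group <- if ("stage" %in% names(cm$cell_meta)) cm$cell_meta$stage
                   else rep("all", ncol(cm$counts))
  set.seed(seed)
  samples <- cm$cell_meta$sample
  for (grp in unique(stage_group)) {
    gi <- stage_group == grp
    tots <- tapply(Matrix::colSums(cm$counts)[gi], samples[gi], sum)
    if (length(tots) < 2) next
    mn <- min(tots)
    for (s in names(tots)) {
      p <- mn / tots[[s]]
      if (p >= 1) next
      ci <- which(gi & samples == s)
      for (ln in c("counts", "spliced", "unspliced")) {
        if (is.null(cm[[ln]])) next
        m <- cm[[ln]][, ci, drop = FALSE]
        m@x <- as.numeric(stats::rbinom(length(m@x), m@x, p))
        cm[[ln]][, ci] <- Matrix::drop0(m)
      }
    }
  }
  cm
}
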