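#' Single-cell count container with optional spliced/unspliced layers
#'
#' A light genes-by-cells container holding an integer count matrix,
#' optional parallel spliced/unspliced layers (same dimensions), per-cell
#' metadata (sample, genotype, stage) and per-gene metadata (chromosome,
#' strand, TSS, mitochondrial flag, optional positional-cluster index).
#'
#' @param counts genes x cells matrix (dense or \code{dgCMatrix}) of
#'   non-negative integer counts; rownames are gene ids, colnames barcodes.
#' @param cell_meta data.frame with one row per cell; must contain a
#'   \code{barcode} column; typically also \code{sample}, \code{genotype},
#'   \code{stage}.
#' @param gene_meta data.frame with one row per gene; must contain a
#'   \code{gene} column; typically also \code{chromosome}, \code{strand},
#'   \code{tss}, \code{mito}.
#' @param spliced,unspliced optional layers with the same dimensions as
#'   \code{counts}.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL,
                         spliced = NULL, unspliced = NULL) {
  counts <- to_dgc(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (is.null(cell_meta))
    cell_meta <- data.frame(barcode = colnames(counts))
  if (is.null(gene_meta))
    gene_meta <- data.frame(gene = rownames(counts))
  stopifnot(nrow(cell_meta) == ncol(counts), nrow(gene_meta) == nrow(counts))
  if (!"barcode" %in% names(cell_meta)) stop("cell_meta needs a 'barcode' column")
  if (!"gene" %in% names(gene_meta)) stop("gene_meta needs a 'gene' column")
  for (lname in c("spliced", "unspliced")) {
    layer <- get(lname)
    if (!is.null(layer) && !identical(dim(layer), dim(counts)))
      stop("layer '", lname, "' has dimensions incompatible with counts")
  }
  if (any(counts@x < 0)) stop("counts must be non-negative")
  structure(list(
    counts = counts,
    spliced = if (is.null(spliced)) NULL else to_dgc(spliced),
    unspliced = if (is.null(unspliced)) NULL else to_dgc(unspliced),
    cell_meta = cell_meta,
    gene_meta = gene_meta
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  layers:", paste(c("counts",
                           if (!is.null(x$spliced)) "spliced",
                           if (!is.null(x$unspliced)) "unspliced"),
                         collapse = ", "), "\n")
  if ("genotype" %in% names(x$cell_meta))
    cat("  genotypes:", paste(names(table(x$cell_meta$genotype)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count_matrix by cells (and optionally genes)
#'
#' @param cm a \code{count_matrix}
#' @param cells logical/integer/character index over cells
#' @param genes logical/integer/character index over genes
#' @return the subset \code{count_matrix}
#' @export
subset_cells <- function(cm, cells, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  sub <- function(m) if (is.null(m)) NULL else m[genes, cells, drop = FALSE]
  out <- count_matrix(sub(cm$counts),
                      cell_meta = cm$cell_meta[index_to_int(cells, colnames(cm$counts)), , drop = FALSE],
                      gene_meta = cm$gene_meta[index_to_int(genes, rownames(cm$counts)), , drop = FALSE],
                      spliced = sub(cm$spliced), unspliced = sub(cm$unspliced))
  out
}

to_dgc <- function(m) {
  dn <- dimnames(m)
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(m), "CsparseMatrix"),
                               "generalMatrix"), "dMatrix")
  dimnames(m) <- dn
  m
}

# resolve any index flavor to integer positions
index_to_int <- function(idx, nms) {
  if (is.logical(idx)) which(idx)
  else if (is.character(idx)) match(idx, nms)
  else as.integer(idx)
}
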