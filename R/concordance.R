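#' One-sided Fisher exact test (hypergeometric tail) on a 2x2 table
#'
#' Tests enrichment (alternative "greater" for the top-left cell) via the
#' closed-form hypergeometric tail, and reports the sample odds ratio.
#'
#' @param a,b,c_,d_ the 2x2 counts: a = feature & selected, b = feature &
#'   not selected, c_ = no feature & selected, d_ = neither.
#' @return list(p, odds_ratio); any zero margin yields p = 1 with a
#'   warning.
#' @export
fisher_enrichment <- function(a, b, c_, d_) {
  N <- a + b + c_ + d_
  K <- a + b      # feature total
  nsel <- a + c_  # selected total
  if (K == 0 || nsel == 0 || K == N || nsel == N) {
    warning("a margin of the 2x2 table is zero; p = 1")
    return(list(p = 1, odds_ratio = NA_real_))
  }
  p <- stats::phyper(a - 1, K, N - K, nsel, lower.tail = FALSE)
  or <- (a * d_) / (b * c_)
  list(p = p, odds_ratio = or)
}

#' Direction-stratified DEG overlap with one-sided binomial tests
#'
#' For each direction (up, down), counts how many of this study's DEGs are
#' also DEGs of the same direction in an external study, reports the
#' percentage, and tests overrepresentation with a one-sided binomial
#' test whose success probability is the external DEG density of that
#' direction in the shared tested universe.
#'
#' @param self_degs data.frame(gene, direction) with direction in
#'   \{"up","down"\}.
#' @param external_degs data.frame(gene, direction), same convention.
#' @param universe character vector: all genes tested in both studies.
#' @return list of class \code{concordance_report}: \code{overlap}
#'   data.frame(direction, n_self, n_external, n_shared, percent,
#'   binom_p), \code{direction_table} 2x2 agreement counts over genes
#'   that are DEGs in both studies.
#' @export
deg_overlap <- function(self_degs, external_degs, universe) {
  if (!length(universe)) stop("empty tested-gene universe")
  self_degs <- self_degs[self_degs$gene %in% universe, ]
  external_degs <- external_degs[external_degs$gene %in% universe, ]
  rows <- lapply(c("up", "down"), function(d) {
    s <- self_degs$gene[self_degs$direction == d]
    e <- external_degs$gene[external_degs$direction == d]
    k <- length(intersect(s, e))
    p_ext <- length(e) / length(universe)
    bp <- if (length(s) == 0 || p_ext == 0) NA_real_
          else stats::pbinom(k - 1, length(s), p_ext, lower.tail = FALSE)
    data.frame(direction = d, n_self = length(s), n_external = length(e),
               n_shared = k,
               percent = if (length(s)) 100 * k / length(s) else NA_real_,
               binom_p = bp)
  })
  shared_genes <- intersect(self_degs$gene, external_degs$gene)
  ds <- self_degs$direction[match(shared_genes, self_degs$gene)]
  de <- external_degs$direction[match(shared_genes, external_degs$gene)]
  dtab <- table(factor(ds, c("up", "down")), factor(de, c("up", "down")),
                dnn = c("self", "external"))
  structure(list(overlap = do.call(rbind, rows), direction_table = dtab),
            class = "concordance_report")
}

#' Fold-change concordance regression
#'
#' Ordinary least squares of this study's log2 fold changes on an external
#' study's, over shared genes; an attenuation slope near 1 with high r
#' indicates concordant effects.
#'
#' @param lfc_self,lfc_external named numeric vectors of log2 fold
#'   changes.
#' @param genes optional shared genes; default the intersection of names.
#' @return list(slope, intercept, r, n).
#' @export
foldchange_regression <- function(lfc_self, lfc_external, genes = NULL) {
  if (is.null(genes)) genes <- intersect(names(lfc_self), names(lfc_external))
  if (length(genes) < 3) stop("need >= 3 shared genes")
  x <- lfc_external[genes]; y <- lfc_self[genes]
  if (stats::sd(x) == 0) stop("zero-variance predictor fold changes")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(genes))
}

#' Annotate genes by peaks near their TSS
#'
#' A gene has a binding site when any peak overlaps the closed window of
#' +/- \code{window_nt} around its strand-aware TSS (TSS = interval start
#' on +, interval end on -). Gene models and peaks use the BED convention
#' (0-based, half-open).
#'
#' @param gene_models data.frame(gene, chromosome, strand, start, end) or
#'   (gene, chromosome, strand, tss), 0-based.
#' @param peaks data.frame(chromosome, start, end), BED half-open.
#' @param window_nt window half-width in nucleotides (default 250).
#' @return data.frame(gene, tss, has_site, n_sites); warns about peak
#'   chromosomes absent from the gene models.
#' @export
annotate_tss_peaks <- function(gene_models, peaks, window_nt = 250) {
  gm <- gene_models
  if (!"tss" %in% names(gm)) {
    stopifnot(all(c("start", "end") %in% names(gm)))
    gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end - 1L)
  }
  extra <- setdiff(unique(peaks$chromosome), unique(gm$chromosome))
  if (length(extra))
    warning(length(extra), " peak chromosome(s) absent from gene models: ",
            paste(extra, collapse = ", "))
  # 1-based closed coordinates for IRanges
  win <- GenomicRanges::GRanges(
    seqnames = gm$chromosome,
    ranges = IRanges::IRanges(start = gm$tss + 1L - window_nt,
                              end = gm$tss + 1L + window_nt))
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chromosome,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  # the explicit chromosome warning above covers the mismatch case; the
  # seqlevel notice findOverlaps would add is redundant
  n_sites <- suppressWarnings(GenomicRanges::countOverlaps(win, pk))
  data.frame(gene = gm$gene, tss = gm$tss,
             has_site = n_sites >= 1, n_sites = as.integer(n_sites),
             row.names = NULL)
}

#' Binding-site enrichment among differentially expressed genes
#'
#' One-sided Fisher exact test of the 2x2 table (DEG vs non-DEG) x (site
#' vs no site) over the tested universe, overall and optionally per DEG
#' direction.
#'
#' @param deg_genes character vector of DEGs.
#' @param annotation \code{\link{annotate_tss_peaks}} result.
#' @param universe all tested genes (must be annotated).
#' @param directions optional named list of DEG subsets (e.g. up/down) to
#'   test separately.
#' @return data.frame(set, n_deg, n_deg_with_site, odds_ratio, p).
#' @export
binding_site_enrichment <- function(deg_genes, annotation, universe,
                                    directions = NULL) {
  ann <- annotation[annotation$gene %in% universe, ]
  site <- stats::setNames(ann$has_site, ann$gene)
  run <- function(genes, name) {
    genes <- intersect(genes, universe)
    a <- sum(site[genes]); b <- sum(site[setdiff(universe, genes)])
    c_ <- length(genes) - a
    d_ <- length(universe) - length(genes) - b
    fe <- fisher_enrichment(a, b, c_, d_)
    data.frame(set = name, n_deg = length(genes), n_deg_with_site = a,
               odds_ratio = fe$odds_ratio, p = fe$p)
  }
  out <- run(deg_genes, "all")
  for (nm in names(directions)) out <- rbind(out, run(directions[[nm]], nm))
  out
}

#' Gene-set overrepresentation analysis (Fisher + Bonferroni)
#'
#' One-sided Fisher exact test per gene set on the 2x2 table of membership
#' vs interest within the universe; Q is Bonferroni (or BH) across the
#' sets tested. The overrepresentation score is
#' log2((observed + 0.5) / (expected + 0.5)).
#'
#' @param genes_of_interest character vector.
#' @param gene_sets named list of character vectors.
#' @param universe all candidate genes.
#' @param correction "bonferroni" (default) or "BH".
#' @return data.frame(set, n_set, n_overlap, expected, score, p, Q);
#'   sets with empty universe intersection are skipped (noted in the
#'   \code{skipped} attribute).
#' @export
ora <- function(genes_of_interest, gene_sets, universe,
                correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  goi <- intersect(genes_of_interest, universe)
  sets <- lapply(gene_sets, intersect, universe)
  skipped <- names(sets)[lengths(sets) == 0]
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no gene set intersects the universe")
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    a <- length(intersect(goi, s))
    b <- length(s) - a
    c_ <- length(goi) - a
    d_ <- length(universe) - length(s) - c_
    fe <- fisher_enrichment(a, b, c_, d_)
    expd <- length(s) * length(goi) / length(universe)
    data.frame(set = nm, n_set = length(s), n_overlap = a, expected = expd,
               score = log2((a + 0.5) / (expd + 0.5)), p = fe$p)
  })
  out <- do.call(rbind, rows)
  out$Q <- if (correction == "bonferroni") pmin(1, out$p * nrow(out))
           else stats::p.adjust(out$p, "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Permutation GSEA (weighted running-sum, gene-label permutations)
#'
#' Runs preranked gene set enrichment with the weighted (exponent 1)
#' Kolmogorov-Smirnov running-sum statistic and a seeded gene-label
#' permutation null; NES is ES divided by the mean |null ES| of matching
#' sign, with Benjamini-Hochberg Q across sets.
#'
#' @param stats_ranked named numeric vector: the ranking statistic, finite
#'   for all genes.
#' @param gene_sets named list of character vectors; sets smaller than
#'   \code{min_size} after intersection are skipped.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param min_size minimum set size (default 5).
#' @return data.frame(set, size, ES, NES, p, Q).
#' @export
gsea <- function(stats_ranked, gene_sets, n_perm = 10000, seed = 1,
                 min_size = 5) {
  if (any(!is.finite(stats_ranked))) stop("ranking statistic must be finite")
  set.seed(seed)
  res <- suppressWarnings(
    fgsea::fgseaSimple(pathways = gene_sets, stats = stats_ranked,
                       nperm = n_perm, minSize = min_size,
                       maxSize = length(stats_ranked), gseaParam = 1))
  data.frame(set = res$pathway, size = res$size, ES = res$ES, NES = res$NES,
             p = res$pval, Q = stats::p.adjust(res$pval, "BH"))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Read peaks from a BED/narrowPeak file
#'
#' @param path BED file; first three columns chromosome, start, end
#'   (0-based half-open).
#' @return data.frame(chromosome, start, end).
#' @export
read_bed_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("chromosome", "start", "end"))
}
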