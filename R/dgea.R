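#' Vectorized two-sided Mann-Whitney U test
#'
#' U is computed from rank sums. Instances with min(nA, nB) <= 8 and no
#' ties use the exact null distribution; larger or tied instances use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param xa,xb numeric vectors (group A, group B).
#' @return list(U, p): U is the Mann-Whitney statistic for group A.
#' @export
mann_whitney_u <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  if (na == 0 || nb == 0) stop("empty group")
  r <- rank(c(xa, xb))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- rle(sort(c(xa, xb)))$lengths
  has_ties <- any(ties > 1)
  if (min(na, nb) <= 8 && !has_ties) {
    mu <- na * nb / 2
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
    } else if (U < mu) {
      2 * stats::pwilcox(U, na, nb)
    } else 1
    p <- min(1, p)
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Mann-Whitney differential gene expression with Bonferroni control
#'
#' Tests every gene expressed in at least \code{min_frac} of either group
#' (lowly expressed genes are excluded before testing and before the
#' Bonferroni denominator). Fold change is the ratio of expm1 of the mean
#' log-normalized expression, with a small pseudocount.
#'
#' @param logmat genes x cells log-normalized expression.
#' @param cells_a,cells_b column indices (or barcodes) of the two groups,
#'   each of size >= 3.
#' @param min_frac minimum detection fraction in either group (default
#'   0.1).
#' @param pseudo pseudocount in the fold-change ratio.
#' @return data.frame(gene, mean_a, mean_b, fold_change, U, p, Q,
#'   direction) for tested genes, with attribute \code{n_tested} (the
#'   Bonferroni denominator m).
#' @export
mann_whitney_dgea <- function(logmat, cells_a, cells_b, min_frac = 0.1,
                              pseudo = 1e-9) {
  A <- logmat[, cells_a, drop = FALSE]
  B <- logmat[, cells_b, drop = FALSE]
  if (ncol(A) < 3 || ncol(B) < 3) stop("both groups need >= 3 cells")
  det_a <- rowMeans(A > 0); det_b <- rowMeans(B > 0)
  tested <- which(det_a >= min_frac | det_b >= min_frac)
  m <- length(tested)
  if (m == 0) stop("no gene passes the expression filter")
  res <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("U", "p")))
  for (i in seq_len(m)) {
    g <- tested[i]
    mw <- mann_whitney_u(A[g, ], B[g, ])
    res[i, ] <- c(mw$U, mw$p)
  }
  mean_a <- rowMeans(A)[tested]; mean_b <- rowMeans(B)[tested]
  fc <- (expm1(mean_a) + pseudo) / (expm1(mean_b) + pseudo)
  out <- data.frame(
    gene = rownames(logmat)[tested],
    mean_a = mean_a, mean_b = mean_b, fold_change = fc,
    U = res[, "U"], p = res[, "p"],
    Q = pmin(1, res[, "p"] * m),
    direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none")),
    row.names = NULL)
  attr(out, "n_tested") <- m
  out
}

#' Per-sample composition table with Welch t tests
#'
#' Computes each sample's population proportions over the chosen
#' denominator (populations absent from a sample contribute 0, not NA)
#' and compares the genotype groups per population with a two-sided Welch
#' t test on the sample-proportion vectors.
#'
#' @param labels population label per cell.
#' @param sample_ids sample id per cell.
#' @param genotypes genotype per cell (two levels).
#' @param denominator optional logical mask of cells forming each sample's
#'   denominator (e.g. germ-layer cells only); default all cells.
#' @return list: \code{proportions} data.frame(sample, genotype,
#'   population, n_cells, proportion), \code{tests}
#'   data.frame(population, mean_1, sem_1, mean_2, sem_2, t, p) where
#'   groups 1/2 follow the sorted genotype levels.
#' @export
composition_test <- function(labels, sample_ids, genotypes,
                             denominator = NULL) {
  if (is.null(denominator)) denominator <- rep(TRUE, length(labels))
  labels <- as.character(labels)[denominator]
  sample_ids <- as.character(sample_ids)[denominator]
  genotypes <- as.character(genotypes)[denominator]
  glev <- sort(unique(genotypes))
  if (length(glev) != 2) stop("need exactly two genotypes")
  samples <- sort(unique(sample_ids))
  geno_of <- vapply(samples, function(s)
    genotypes[match(s, sample_ids)], character(1))
  if (any(table(geno_of) < 2)) stop("need >= 2 samples per genotype")
  pops <- sort(unique(labels))
  prop_mat <- t(vapply(samples, function(s) {
    tab <- table(factor(labels[sample_ids == s], levels = pops))
    as.numeric(tab) / sum(tab)
  }, numeric(length(pops))))
  colnames(prop_mat) <- pops
  count_mat <- t(vapply(samples, function(s)
    as.numeric(table(factor(labels[sample_ids == s], levels = pops))),
    numeric(length(pops))))
  props <- do.call(rbind, lapply(seq_along(samples), function(i)
    data.frame(sample = samples[i], genotype = geno_of[i],
               population = pops, n_cells = count_mat[i, ],
               proportion = prop_mat[i, ], row.names = NULL)))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tests <- do.call(rbind, lapply(pops, function(pp) {
    x1 <- prop_mat[geno_of == glev[1], pp]
    x2 <- prop_mat[geno_of == glev[2], pp]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      # degenerate but well-defined: identical constants are a perfect null
      tstat <- if (mean(x1) == mean(x2)) 0 else Inf
      pval <- if (mean(x1) == mean(x2)) 1 else 0
    } else {
      tt <- stats::t.test(x1, x2)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(population = pp,
               mean_1 = mean(x1), sem_1 = sem(x1),
               mean_2 = mean(x2), sem_2 = sem(x2),
               t = tstat, p = pval, row.names = NULL)
  }))
  attr(tests, "genotype_levels") <- glev
  list(proportions = props, tests = tests)
}

#' Chi-square test of driver-gene expression direction against 50/50
#'
#' Given the counts of significantly under- and overexpressed driver
#' genes, tests the 1-df chi-square against an even split.
#'
#' @param n_under,n_over counts of underexpressed and overexpressed
#'   drivers (Q < 0.05 genes intersected with the driver set).
#' @return list(n_under, n_over, expected, statistic, p); NA with a
#'   warning when both counts are zero.
#' @export
driver_direction_chisq <- function(n_under, n_over) {
  n <- n_under + n_over
  if (n == 0) {
    warning("no significant driver gene in either direction")
    return(list(n_under = 0, n_over = 0, expected = 0,
                statistic = NA_real_, p = NA_real_))
  }
  e <- n / 2
  stat <- (n_under - e)^2 / e + (n_over - e)^2 / e
  list(n_under = n_under, n_over = n_over, expected = e,
       statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Count significant driver directions from a DGEA table
#'
#' Restricts a genotype DGEA result to Q < 0.05 genes within a driver set
#' and counts under- vs overexpression (direction of group A relative to
#' group B), then applies \code{\link{driver_direction_chisq}}.
#'
#' @param drivers character vector of driver gene names.
#' @param dgea a \code{\link{mann_whitney_dgea}} result where group A is
#'   the genotype of interest.
#' @param alpha significance cutoff on Q.
#' @return as \code{\link{driver_direction_chisq}}.
#' @export
driver_chisq_from_dgea <- function(drivers, dgea, alpha = 0.05) {
  sig <- dgea[dgea$Q < alpha & dgea$gene %in% drivers, ]
  driver_direction_chisq(sum(sig$direction == "down"),
                         sum(sig$direction == "up"))
}

#' Positional (chromosomally ordered) expression profile
#'
#' Mean and SEM per gene and group, with rows in exactly the supplied gene
#' order (e.g. 5' to 3' chromosomal position of a Hox-like cluster), for
#' comparing activation timing across groups.
#'
#' @param logmat genes x cells log-normalized expression.
#' @param ordered_genes gene names in the desired order.
#' @param groups group label per cell.
#' @return data.frame(gene, position, group, mean, sem); genes missing
#'   from the matrix are kept as NA rows and reported in a warning.
#' @export
positional_expression_profile <- function(logmat, ordered_genes, groups) {
  if (!length(ordered_genes)) stop("empty gene list")
  missing <- setdiff(ordered_genes, rownames(logmat))
  if (length(missing))
    warning("genes missing from the matrix: ", paste(missing, collapse = ", "))
  glev <- if (is.factor(groups)) levels(groups)
          else sort(unique(as.character(groups)))
  groups <- as.character(groups)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list()
  for (i in seq_along(ordered_genes)) {
    g <- ordered_genes[i]
    for (grp in glev) {
      x <- if (g %in% rownames(logmat)) logmat[g, groups == grp] else NA_real_
      out[[length(out) + 1]] <- data.frame(
        gene = g, position = i, group = grp,
        mean = mean(x), sem = if (all(is.na(x))) NA_real_ else sem(x))
    }
  }
  do.call(rbind, out)
}
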