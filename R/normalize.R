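#' Negative-binomial Pearson-residual normalization
#'
#' Models each count with mean mu_gj = (gene total x cell total) / grand
#' total and a per-gene negative-binomial dispersion estimated by the
#' method of moments, then regularized by a loess fit of log dispersion
#' against log mean expression. Returns clipped Pearson residuals
#' (x - mu) / sqrt(mu + mu^2/theta), the depth-invariant working data for
#' dimensionality reduction. Zero-count genes get all-zero residuals and
#' are flagged in the \code{zero_genes} attribute.
#'
#' @param counts genes x cells count matrix (or a \code{count_matrix}).
#' @param clip residual clipping bound; default sqrt(n_cells).
#' @param theta_max cap on the dispersion parameter (the Poisson limit).
#' @return dense genes x cells residual matrix with attributes
#'   \code{theta} (regularized per-gene dispersion) and \code{zero_genes}.
#' @export
normalize_pearson <- function(counts, clip = NULL, theta_max = 1e6) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  X <- as.matrix(counts)
  n <- ncol(X)
  if (is.null(clip)) clip <- sqrt(n)
  gs <- rowSums(X); cs <- colSums(X); tot <- sum(X)
  if (tot == 0) stop("all-zero count matrix")
  mu <- outer(gs, cs) / tot
  zero <- gs == 0
  # method-of-moments theta: E[(x-mu)^2] = mean(mu) + mean(mu^2)/theta
  ssq <- rowMeans((X - mu)^2)
  mmu <- rowMeans(mu); mmu2 <- rowMeans(mu^2)
  theta_raw <- ifelse(ssq > mmu, mmu2 / (ssq - mmu), theta_max)
  theta_raw <- pmin(pmax(theta_raw, 1e-3), theta_max)
  # regularize log10(theta) vs log10(mean) over expressed genes
  ok <- !zero & mmu > 0
  theta <- theta_raw
  if (sum(ok) >= 20) {
    df <- data.frame(lth = log10(theta_raw[ok]), lmu = log10(mmu[ok]))
    lf <- tryCatch(stats::loess(lth ~ lmu, data = df, span = 0.75, degree = 2),
                   error = function(e) NULL)
    if (!is.null(lf)) {
      pr <- stats::predict(lf, newdata = data.frame(lmu = df$lmu))
      good <- is.finite(pr)
      theta[ok][good] <- pmin(pmax(10^pr[good], 1e-3), theta_max)
    }
  }
  res <- (X - mu) / sqrt(mu + mu^2 / theta)
  res[zero, ] <- 0
  res[!is.finite(res)] <- 0
  res <- pmin(pmax(res, -clip), clip)
  dimnames(res) <- dimnames(counts)
  attr(res, "theta") <- theta
  attr(res, "zero_genes") <- rownames(counts)[zero]
  res
}

#' Library-size log normalization
#'
#' log1p of counts scaled to the median library size; the rank-preserving
#' per-gene values used for Mann-Whitney testing, fold changes and driver
#' correlations.
#'
#' @param counts genes x cells count matrix (or a \code{count_matrix}).
#' @param scale_to target library size (default median of the cell totals).
#' @return dense genes x cells matrix of log-normalized expression.
#' @export
normalize_log <- function(counts, scale_to = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  cs <- Matrix::colSums(counts)
  if (is.null(scale_to)) scale_to <- stats::median(cs[cs > 0])
  fac <- ifelse(cs > 0, scale_to / cs, 0)
  out <- as.matrix(counts %*% Matrix::Diagonal(x = fac))
  dimnames(out) <- dimnames(counts)
  log1p(out)
}

#' Select highly variable genes by normalized dispersion
#'
#' Computes per-gene mean and dispersion (variance/mean) of expm1 of the
#' log-normalized matrix, z-scores dispersion within mean bins, and takes
#' the top genes.
#'
#' @param logmat genes x cells log-normalized matrix.
#' @param n_top number of genes to keep (default 2000).
#' @param n_bins number of mean-expression bins.
#' @return character vector of gene names, ordered by decreasing
#'   normalized dispersion.
#' @export
variable_genes <- function(logmat, n_top = 2000, n_bins = 20) {
  X <- expm1(logmat)
  mu <- rowMeans(X)
  v <- apply(X, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- mu > 0 & disp > 0
  if (!any(keep)) stop("no expressed, variable gene")
  br <- unique(stats::quantile(mu[keep], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- rep(NA_real_, length(mu))
  for (b in levels(bin)) {
    bi <- which(bin == b & keep)
    if (length(bi) < 2) { z[bi] <- 0; next }
    m <- mean(disp[bi]); s <- stats::sd(disp[bi])
    z[bi] <- if (s > 0) (disp[bi] - m) / s else 0
  }
  ord <- order(z, decreasing = TRUE, na.last = TRUE)
  head(rownames(logmat)[ord][keep[ord]], n_top)
}
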