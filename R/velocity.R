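#' Steady-state RNA velocity from spliced/unspliced counts
#'
#' kNN-smooths both layers over cells, estimates each gene's
#' degradation/splicing ratio gamma-hat by least squares through the
#' origin on the cells in the extreme (top/bottom) quantiles of smoothed
#' spliced abundance, and defines velocity v = u - gamma-hat * s on the
#' smoothed values. Genes with too few nonzero cells in either layer are
#' excluded.
#'
#' @param spliced,unspliced genes x cells count matrices (same shape).
#' @param k_smooth neighbors for count smoothing (including self).
#' @param embedding optional cells x dims space for the smoothing kNN;
#'   default PCA (30 components) of log-normalized spliced counts.
#' @param gamma_method "ratio" (default): gamma-hat = sum(u)/sum(s) over
#'   all cells, the moment-ratio estimator, exact whenever cells are a
#'   mixture of per-population steady states; "extreme": least squares
#'   through the origin on the cells in the extreme quantiles of s (the
#'   classical steady-state fit, attenuated by noise in s).
#' @param extreme_q quantile defining the extreme cells used by the
#'   "extreme" gamma fit (default 0.05: top and bottom 5%).
#' @param min_cells minimum nonzero cells per layer for a gene to be
#'   fitted (default 10).
#' @return list of class \code{velocity_model}: \code{gamma} (per fitted
#'   gene), \code{velocity} (fitted genes x cells), \code{Ms}, \code{Mu}
#'   smoothed layers, \code{fitted_genes}, \code{embedding}.
#' @export
estimate_velocity <- function(spliced, unspliced, k_smooth = 15,
                              embedding = NULL,
                              gamma_method = c("ratio", "extreme"),
                              extreme_q = 0.05, min_cells = 10) {
  gamma_method <- match.arg(gamma_method)
  if (!identical(dim(spliced), dim(unspliced)))
    stop("spliced and unspliced layers must have the same shape")
  n <- ncol(spliced)
  if (is.null(embedding)) {
    lg <- normalize_log(spliced)
    pcs <- select_pcs(lg, k_mad = 0, max_pcs = 30)
    embedding <- pcs$scores[, seq_len(min(30, ncol(pcs$scores))), drop = FALSE]
  }
  knn <- knn_index(embedding, min(k_smooth, n - 1))
  # smoothing operator: average over self + neighbors
  k <- ncol(knn$index)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                            j = c(as.vector(knn$index), seq_len(n)),
                            x = 1 / (k + 1), dims = c(n, n))
  Ms <- as.matrix(Matrix::tcrossprod(methods::as(spliced, "CsparseMatrix"), A))
  Mu <- as.matrix(Matrix::tcrossprod(methods::as(unspliced, "CsparseMatrix"), A))
  dimnames(Ms) <- dimnames(Mu) <- dimnames(spliced)
  nz_s <- Matrix::rowSums(spliced > 0); nz_u <- Matrix::rowSums(unspliced > 0)
  fitted <- which(nz_s >= min_cells & nz_u >= min_cells)
  if (!length(fitted)) stop("no gene has enough nonzero cells to fit")
  gamma <- numeric(length(fitted))
  for (i in seq_along(fitted)) {
    g <- fitted[i]
    s <- Ms[g, ]; u <- Mu[g, ]
    if (gamma_method == "ratio") {
      # moment ratio: exact for any mixture of per-population steady
      # states, and free of the selection bias that least squares on
      # noisy extreme cells suffers
      gamma[i] <- if (sum(s) > 0) sum(u) / sum(s) else NA_real_
    } else {
      qs <- stats::quantile(s, c(extreme_q, 1 - extreme_q))
      ext <- which(s <= qs[1] | s >= qs[2])
      denom <- sum(s[ext]^2)
      gamma[i] <- if (denom > 0) sum(u[ext] * s[ext]) / denom else NA_real_
    }
  }
  ok <- is.finite(gamma) & gamma > 0
  fitted <- fitted[ok]; gamma <- gamma[ok]
  if (!length(fitted)) stop("no gene yielded a positive gamma estimate")
  v <- Mu[fitted, , drop = FALSE] - gamma * Ms[fitted, , drop = FALSE]
  structure(list(gamma = stats::setNames(gamma, rownames(spliced)[fitted]),
                 velocity = v, Ms = Ms, Mu = Mu,
                 fitted_genes = rownames(spliced)[fitted],
                 embedding = embedding),
            class = "velocity_model")
}

#' Velocity-directed transition matrix
#'
#' For each cell, transition probabilities over its kNN neighbors are
#' softmax-weighted cosine similarities between the cell's velocity
#' vector and the expression displacement toward each neighbor (both in
#' the fitted-gene smoothed expression space). Cells with zero velocity
#' get uniform transitions over their neighbors and are flagged.
#'
#' @param model a \code{\link{estimate_velocity}} result.
#' @param k_neighbors kNN size (graph built in \code{model$embedding}).
#' @param kernel_scale softmax temperature on the cosine score (default
#'   0.1).
#' @param stabilize variance-stabilize the gene dimension (divide each
#'   gene's velocity and displacement by sqrt(mean expression + 1)) before
#'   the cosine, so the score is not dominated by shot noise of
#'   high-expression genes (default TRUE).
#' @return sparse row-stochastic \code{dgCMatrix} with attribute
#'   \code{zero_velocity_cells}.
#' @export
velocity_transition_matrix <- function(model, k_neighbors = 15,
                                       kernel_scale = 0.1,
                                       stabilize = TRUE) {
  emb <- model$embedding
  n <- nrow(emb)
  knn <- knn_index(emb, min(k_neighbors, n - 1))
  k <- ncol(knn$index)
  X <- model$Ms[model$fitted_genes, , drop = FALSE]
  V <- model$velocity
  if (stabilize) {
    # per-gene Poisson-scale weights so high-expression genes' shot noise
    # does not dominate the cosine
    w <- 1 / sqrt(rowMeans(X) + 1)
    X <- X * w
    V <- V * w
  }
  ii <- jj <- xx <- vector("list", n)
  zerov <- integer(0)
  for (i in seq_len(n)) {
    nb <- knn$index[i, ]
    dx <- X[, nb, drop = FALSE] - X[, i]
    vi <- V[, i]
    nv <- sqrt(sum(vi^2))
    nd <- sqrt(colSums(dx^2))
    if (nv == 0 || all(nd == 0)) {
      p <- rep(1 / k, k)
      zerov <- c(zerov, i)
    } else {
      cs <- as.numeric(crossprod(vi, dx)) / (nv * pmax(nd, 1e-12))
      cs[nd == 0] <- 0
      e <- exp((cs - max(cs)) / kernel_scale)
      p <- e / sum(e)
    }
    ii[[i]] <- rep(i, k); jj[[i]] <- nb; xx[[i]] <- p
  }
  T_ <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n, n))
  attr(T_, "zero_velocity_cells") <- zerov
  T_
}

#' Absorption probabilities to terminal fates (exact linear solve)
#'
#' Terminal cells are made absorbing; with Q the transient-to-transient
#' and R the transient-to-absorbing blocks of the transition matrix, the
#' fate-probability matrix solves (I - Q) B = R (columns aggregated by
#' fate). Terminal rows are their own fate indicator; every row sums
#' to 1.
#'
#' @param T_ row-stochastic cells x cells transition matrix.
#' @param terminal character (or factor) vector, one entry per cell: the
#'   terminal fate label, or NA for transient cells.
#' @return cells x fates matrix of class \code{fate_probabilities};
#'   errors listing transient cells that cannot reach any terminal cell.
#' @export
absorption_probabilities <- function(T_, terminal) {
  n <- nrow(T_)
  stopifnot(length(terminal) == n)
  terminal <- as.character(terminal)
  fates <- sort(unique(terminal[!is.na(terminal)]))
  if (!length(fates)) stop("need at least one terminal fate")
  is_term <- !is.na(terminal)
  # reachability: iterate reverse closure from the terminal set
  Adj <- methods::as(T_ > 0, "CsparseMatrix") * 1
  reach <- is_term
  repeat {
    new <- (as.numeric(Adj %*% reach) > 0) & !reach
    if (!any(new)) break
    reach <- reach | new
  }
  if (!all(reach)) {
    bad <- which(!reach)
    stop("transient cells with no path to any terminal state: ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "")
  }
  trans <- which(!is_term); term <- which(is_term)
  B <- matrix(0, n, length(fates), dimnames = list(rownames(T_), fates))
  B[cbind(term, match(terminal[term], fates))] <- 1
  if (length(trans)) {
    Qm <- T_[trans, trans, drop = FALSE]
    Rm <- T_[trans, term, drop = FALSE]
    Fi <- Matrix::sparseMatrix(i = seq_along(term),
                               j = match(terminal[term], fates), x = 1,
                               dims = c(length(term), length(fates)))
    Rf <- Rm %*% Fi
    In <- Matrix::Diagonal(length(trans))
    Bt <- Matrix::solve(In - Qm, Rf)
    B[trans, ] <- as.matrix(Bt)
  }
  class(B) <- c("fate_probabilities", class(B))
  B
}

#' Monte-Carlo random-walk estimate of fate probabilities
#'
#' Simulates seeded random walks from every transient cell until
#' absorption in a terminal cell (or \code{max_steps}, counted as
#' censored and reported); the estimate is the fraction of walks absorbed
#' per fate - the independent oracle for
#' \code{\link{absorption_probabilities}}.
#'
#' Walks are routed with balanced (stratified) categorical draws: at each
#' step the walks occupying a state are allocated across its neighbors
#' proportionally to the transition row (integer part deterministic,
#' residual multinomial, assignment randomly permuted within the group).
#' Every individual walk's marginal law is exactly the transition matrix;
#' the balancing only removes between-walk sampling noise, the standard
#' systematic-resampling variance reduction.
#'
#' @param T_ row-stochastic transition matrix.
#' @param terminal terminal fate label per cell, NA for transient.
#' @param n_walks walks per transient cell.
#' @param max_steps cap per walk (default 10 x cells).
#' @param seed RNG seed.
#' @param block transient cells simulated per vectorized block.
#' @return cells x fates matrix; attribute \code{censored_fraction}.
#'   Warns when more than 1% of walks were censored.
#' @export
random_walk_oracle <- function(T_, terminal, n_walks = 1000,
                               max_steps = NULL, seed = 1, block = 300) {
  n <- nrow(T_)
  terminal <- as.character(terminal)
  fates <- sort(unique(terminal[!is.na(terminal)]))
  if (!length(fates)) stop("need at least one terminal fate")
  if (is.null(max_steps)) max_steps <- 10 * n
  set.seed(seed)
  Td <- methods::as(T_, "CsparseMatrix")
  # per-state neighbor lists and probabilities for fast row sampling
  Tt <- Matrix::t(Td)  # column-access = row of T_
  pj <- Tt@p
  nbrs <- vector("list", n); probs <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- (pj[i] + 1):pj[i + 1]
    nbrs[[i]] <- Tt@i[idx] + 1L
    pr <- Tt@x[idx]
    probs[[i]] <- pr / sum(pr)
  }
  is_term <- !is.na(terminal)
  fate_idx <- rep(NA_integer_, n)
  fate_idx[is_term] <- match(terminal[is_term], fates)
  trans <- which(!is_term)
  B <- matrix(0, n, length(fates), dimnames = list(rownames(T_), fates))
  B[cbind(which(is_term), fate_idx[is_term])] <- 1
  # balanced categorical step for all live walks, grouped by state
  step_walks <- function(st) {
    nxt <- integer(length(st))
    ord <- order(st)
    r <- rle(st[ord])
    pos <- 0L
    for (gi in seq_along(r$values)) {
      s <- r$values[gi]; ns <- r$lengths[gi]
      p_row <- probs[[s]]
      base <- floor(p_row * ns)
      rem <- ns - sum(base)
      if (rem > 0) base <- base + as.integer(stats::rmultinom(1, rem, p_row))
      dest <- rep(nbrs[[s]], base)
      grp <- ord[pos + seq_len(ns)]
      nxt[grp[sample.int(ns)]] <- dest
      pos <- pos + ns
    }
    nxt
  }
  censored <- 0; total <- 0
  for (start in seq(1, length(trans), by = block)) {
    cellblock <- trans[start:min(start + block - 1, length(trans))]
    m <- length(cellblock) * n_walks
    origin <- rep(cellblock, each = n_walks)
    state <- rep(cellblock, each = n_walks)
    absorbed_fate <- rep(NA_integer_, m)
    live <- seq_len(m)
    st <- state
    for (step in seq_len(max_steps)) {
      if (!length(st)) break
      nxt <- step_walks(st)
      hit <- is_term[nxt]
      if (any(hit)) {
        absorbed_fate[live[hit]] <- fate_idx[nxt[hit]]
        live <- live[!hit]
        st <- nxt[!hit]
      } else {
        st <- nxt
      }
    }
    censored <- censored + length(st)
    total <- total + m
    done <- !is.na(absorbed_fate)
    for (ci in cellblock) {
      wi <- origin == ci & done
      nf <- tabulate(absorbed_fate[wi], nbins = length(fates))
      B[ci, ] <- if (sum(nf) > 0) nf / sum(nf) else 0
    }
  }
  cf <- censored / total
  if (cf > 0.01)
    warning(sprintf("%.2f%% of walks were censored at max_steps", 100 * cf))
  attr(B, "censored_fraction") <- cf
  B
}

#' Classify lineage driver and antidriver genes
#'
#' Spearman correlation, over a lineage cell subset, between each gene's
#' expression and a fate's absorption probability; genes with rho > 0.25
#' are drivers of that fate, rho < -0.25 antidrivers. Constant genes get
#' an undefined rho and class "neither".
#'
#' @param fate_probs \code{\link{absorption_probabilities}} matrix.
#' @param logmat genes x cells log-normalized expression (same cells).
#' @param fate column name of the fate of interest.
#' @param cells indices of the on-lineage cell subset (off-lineage
#'   populations should be excluded by the caller).
#' @param threshold classification threshold on |rho| (default 0.25).
#' @return data.frame(gene, rho, class) of class \code{driver_table}.
#' @export
lineage_drivers <- function(fate_probs, logmat, fate, cells = NULL,
                            threshold = 0.25) {
  if (is.null(cells)) cells <- seq_len(ncol(logmat))
  y <- fate_probs[cells, fate]
  X <- logmat[, cells, drop = FALSE]
  rho <- suppressWarnings(as.numeric(stats::cor(t(X), y, method = "spearman")))
  cls <- ifelse(is.na(rho), "neither",
                ifelse(rho > threshold, "driver",
                       ifelse(rho < -threshold, "antidriver", "neither")))
  out <- data.frame(gene = rownames(logmat), rho = rho, class = cls,
                    row.names = NULL)
  class(out) <- c("driver_table", class(out))
  out
}

#' Lineage branching signature
#'
#' The genes that are simultaneously drivers of fate A and antidrivers of
#' the sibling fate B: genes whose expression level biases the branch
#' choice. Returns the shared set plus Venn counts and the overlap
#' percentage relative to the antidriver set.
#'
#' @param drivers_a \code{\link{lineage_drivers}} table for fate A.
#' @param antidrivers_b \code{\link{lineage_drivers}} table for fate B
#'   (its "antidriver" rows are used).
#' @return list(signature, n_drivers_a, n_antidrivers_b, n_shared,
#'   pct_of_antidrivers).
#' @export
branching_signature <- function(drivers_a, antidrivers_b) {
  da <- drivers_a$gene[drivers_a$class == "driver"]
  ab <- antidrivers_b$gene[antidrivers_b$class == "antidriver"]
  shared <- intersect(da, ab)
  list(signature = shared,
       n_drivers_a = length(da),
       n_antidrivers_b = length(ab),
       n_shared = length(shared),
       pct_of_antidrivers = if (length(ab)) 100 * length(shared) / length(ab)
                            else NA_real_)
}
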