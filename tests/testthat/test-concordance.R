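test_that("Fisher enrichment p equals exhaustive hypergeometric enumeration", {
  # every 2x2 table with total up to 40, against a dhyper tail sum oracle
  for (N in c(8, 17, 40)) {
    for (K in 1:(N - 1)) {
      for (nsel in 1:(N - 1)) {
        a_max <- min(K, nsel)
        a_min <- max(0, K + nsel - N)
        for (a in a_min:a_max) {
          b <- K - a; c_ <- nsel - a; d_ <- N - K - c_
          got <- suppressWarnings(fisher_enrichment(a, b, c_, d_))
          oracle <- sum(stats::dhyper(a:a_max, K, N - K, nsel))
          expect_equal(got$p, oracle, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fisher enrichment agrees with fisher.test and handles zero margins", {
  ft <- stats::fisher.test(matrix(c(9, 2, 3, 11), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(fisher_enrichment(9, 2, 3, 11)$p, ft$p.value,
               tolerance = 1e-12)
  expect_warning(z <- fisher_enrichment(0, 0, 5, 5))
  expect_equal(z$p, 1)
})

test_that("binomial concordance p equals the closed-form tail for n <= 30", {
  set.seed(13)
  universe <- paste0("g", 1:100)
  for (rep in 1:20) {
    n_ext <- sample(5:40, 1)
    n_self <- sample(3:30, 1)
    ext <- sample(universe, n_ext)
    self <- sample(universe, n_self)
    rep_out <- deg_overlap(
      data.frame(gene = self, direction = "up"),
      data.frame(gene = ext, direction = "up"),
      universe)
    row <- rep_out$overlap[rep_out$overlap$direction == "up", ]
    k <- length(intersect(self, ext))
    p_oracle <- sum(stats::dbinom(k:n_self, n_self, n_ext / 100))
    expect_equal(row$n_shared, k)
    expect_equal(row$binom_p, p_oracle, tolerance = 1e-12)
  }
})

test_that("the worked overlap toy returns 80% and the exact binomial tail", {
  universe <- paste0("g", 1:100)
  ext_up <- paste0("g", 1:20)
  self_up <- paste0("g", c(1:8, 90, 91))   # 10 DEGs, 8 overlapping
  out <- deg_overlap(data.frame(gene = self_up, direction = "up"),
                     data.frame(gene = ext_up, direction = "up"),
                     universe)
  row <- out$overlap[out$overlap$direction == "up", ]
  expect_equal(row$percent, 80)
  expect_equal(row$binom_p, sum(dbinom(8:10, 10, 0.2)), tolerance = 1e-12)
  expect_lt(row$binom_p, 1e-4)
})

test_that("identical DEG sets overlap 100% in both directions", {
  universe <- paste0("g", 1:50)
  degs <- data.frame(gene = paste0("g", 1:20),
                     direction = rep(c("up", "down"), 10))
  out <- deg_overlap(degs, degs, universe)
  expect_true(all(out$overlap$percent == 100))
})

test_that("fold-change regression recovers identity, scaling and a noisy slope", {
  g <- paste0("g", 1:500)
  set.seed(21)
  x <- stats::setNames(rnorm(500, 0, 1), g)
  ident <- foldchange_regression(x, x)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$r, 1, tolerance = 1e-12)
  half <- foldchange_regression(0.5 * x, x)
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  # attenuated external study: slope 0.8 plus noise
  slopes <- replicate(50, {
    y <- stats::setNames(0.8 * x + rnorm(500, 0, 0.3), g)
    foldchange_regression(y, x)$slope
  })
  expect_lt(abs(mean(slopes) - 0.8), 0.05)
  expect_error(foldchange_regression(x, stats::setNames(rep(1, 500), g)),
               "zero-variance")
})

test_that("TSS windows are closed at exactly 250 nt on both strands", {
  gm <- data.frame(gene = c("plus", "minus"),
                   chromosome = "chr1", strand = c("+", "-"),
                   start = c(5000L, 1000L), end = c(6000L, 2000L))
  # plus-strand TSS = 5000; minus-strand TSS = 1999 (0-based)
  # bases 4750 and 2249 lie exactly 250 nt from the TSSs: inside the
  # closed window
  hit_at_250 <- data.frame(chromosome = "chr1",
                           start = c(4750L, 2249L), end = c(4751L, 2250L))
  ann <- annotate_tss_peaks(gm, hit_at_250)
  expect_equal(ann$tss, c(5000L, 1999L))
  expect_true(all(ann$has_site))
  # bases 4749 and 2250 are 251 nt away: outside
  miss_at_251 <- data.frame(chromosome = "chr1",
                            start = c(4749L, 2250L), end = c(4750L, 2251L))
  ann2 <- annotate_tss_peaks(gm, miss_at_251)
  expect_false(any(ann2$has_site))
  # a peak exactly covering each TSS
  cover <- data.frame(chromosome = "chr1",
                      start = c(5000L, 1999L), end = c(5001L, 2000L))
  expect_true(all(annotate_tss_peaks(gm, cover)$has_site))
  # strand-aware worked example: minus-strand gene [1000, 2000), peak
  # [2200, 2260) lies 201 nt downstream of the TSS
  expect_true(annotate_tss_peaks(gm[2, ], data.frame(
    chromosome = "chr1", start = 2200L, end = 2260L))$has_site)
  expect_warning(annotate_tss_peaks(gm, data.frame(
    chromosome = "chrUn", start = 1L, end = 10L)), "chrUn")
})

test_that("binding-site enrichment detects association and stays calibrated under the null", {
  set.seed(31)
  universe <- paste0("g", 1:400)
  site <- rep(c(TRUE, FALSE), c(100, 300))
  ann <- data.frame(gene = universe, tss = 0, has_site = site,
                    n_sites = as.integer(site))
  # enriched: DEGs drawn preferentially from site genes
  degs <- c(sample(universe[site], 60), sample(universe[!site], 30))
  out <- binding_site_enrichment(degs, ann, universe)
  expect_lt(out$p[1], 1e-6)
  expect_gt(out$odds_ratio[1], 1)
  # null calibration: independent flags
  pvals <- replicate(300, {
    degs0 <- sample(universe, 90)
    binding_site_enrichment(degs0, ann, universe)$p[1]
  })
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("ORA ranks the true set first and matches the shared hypergeometric kernel", {
  universe <- paste0("g", 1:200)
  sets <- list(true = universe[1:25],
               other = universe[26:60],
               third = universe[61:80])
  out <- ora(universe[1:25], sets, universe)
  expect_equal(out$set[which.min(out$p)], "true")
  expect_equal(out$Q, pmin(1, out$p * nrow(out)))
  # code-path equivalence with the binding-site Fisher on the same table
  a <- out$n_overlap[out$set == "third"]
  fe <- suppressWarnings(fisher_enrichment(a, 20 - a, 25 - a, 200 - 20 - 25 + a))
  expect_equal(out$p[out$set == "third"], fe$p, tolerance = 1e-12)
})

test_that("GSEA finds a planted top set, flips sign under ranking reversal, and is calibrated", {
  set.seed(41)
  stats_r <- stats::setNames(sort(rnorm(300), decreasing = TRUE),
                             paste0("g", 1:300))
  sets <- list(top = paste0("g", 1:15),
               random = sample(names(stats_r), 20))
  out <- gsea(stats_r, sets, n_perm = 500, seed = 1)
  top <- out[out$set == "top", ]
  expect_gt(top$ES, 0)
  expect_lte(top$p, 1 / (500 / 2))   # near the permutation floor
  out_rev <- gsea(-stats_r, sets, n_perm = 500, seed = 1)
  expect_lt(out_rev$ES[out_rev$set == "top"], 0)
})

test_that("GMT and BED round-trips parse correctly", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(names(sets), c("setA", "setB"))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1\t5", "chr2\t0\t50\tpk2\t1"), bed)
  pk <- read_bed_peaks(bed)
  expect_equal(pk$start, c(100, 0))
  expect_equal(pk$chromosome, c("chr1", "chr2"))
})
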