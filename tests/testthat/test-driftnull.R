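test_that("K matrix equals the definition and a brute-force double-loop oracle", {
  # L = 1: single-term product of deviations
  anc <- matrix(c(0.6, 0.3, 0.9), 1)
  alpha <- c(0.5, 0.4, 0.7)
  km <- compute_K(anc, alpha)
  expect_equal(km$K, outer(anc[1, ] - alpha, anc[1, ] - alpha),
               ignore_attr = TRUE)
  # identical deviations at every locus: covariance = variance, corr = 1
  set.seed(21)
  dev <- rnorm(30, 0, 0.05)
  f2 <- cbind(0.5 + dev, 0.3 + dev)
  km2 <- compute_K(f2, c(0.5, 0.3))
  expect_equal(km2$K[1, 2], km2$K[1, 1])
  expect_equal(km2$corr[1, 2], 1)
  # random 5 x 50 matrix vs naive double loop
  set.seed(22)
  f <- matrix(runif(250), 50, 5)
  al <- runif(5, 0.3, 0.7)
  km3 <- compute_K(f, al)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- mean((f[, i] - al[i]) * (f[, j] - al[j]))
  expect_equal(unname(km3$K), oracle, tolerance = 1e-12)
  # zero-variance population: correlation reported missing
  f4 <- cbind(f[, 1], 0.5)
  km4 <- suppressMessages(compute_K(f4, c(al[1], 0.5)))
  expect_true(is.na(km4$corr[1, 2]))
})

test_that("null simulators honour their degenerate limits", {
  # all individual proportions 1 -> poisson-binomial frequencies exactly 1
  ens <- simulate_null("poisson-binomial",
                       individuals = list(p1 = rep(1, 8), p2 = rep(1, 9)),
                       n_loci = 50, seed = 1)
  expect_true(all(ens$freqs == 1))
  # K = 0: variance-only draws equal alpha exactly
  km0 <- fixture_kmodel()
  km0$K <- matrix(0, 6, 6)
  ens0 <- simulate_null("mvn-variance-only", k_model = km0, n_loci = 40,
                        seed = 2)
  expect_equal(unname(ens0$freqs),
               matrix(km0$alpha, 40, 6, byrow = TRUE))
  # full MVN on a singular K falls back to a ridge with a warning
  expect_warning(simulate_null("mvn-full", k_model = km0, n_loci = 10,
                               seed = 3), "ridge")
})

test_that("full-MVN ensemble moment-matches K and reconverges through compute_K", {
  km <- fixture_kmodel(P = 6, var = 0.01, rho = 0.4)
  ens <- simulate_null("mvn-full", k_model = km, n_loci = 30000, seed = 4)
  # mid-range alphas at sd 0.1: ~3 sigma from the bounds, so truncation
  # stays in the per-mille range
  expect_lt(ens$trunc_low + ens$trunc_high, 0.005)
  khat <- compute_K(ens$freqs, km$alpha)
  expect_lt(max(abs(khat$K - km$K)), 0.001)
  expect_lt(max(abs(diag(khat$K) / diag(km$K) - 1)), 0.05)
})

test_that("truncation moves low-alpha means inward; poisson-binomial variance is below drift variance", {
  # alpha near 0: truncation at the lower bound raises the ensemble mean
  km <- fixture_kmodel()
  km$alpha <- rep(0.03, 6)
  diag(km$K) <- 0.01  # sd 0.1 >> alpha: substantial lower truncation
  ens <- simulate_null("mvn-full", k_model = km, n_loci = 20000, seed = 5)
  expect_gt(ens$trunc_low, 0.1)
  expect_gt(min(colMeans(ens$freqs)), 0.03)
  # drift variance exceeding binomial sampling variance: pb < variance-only
  a <- rep(0.5, 10)
  kmb <- fixture_kmodel()
  kmb$alpha <- 0.5
  kmb$K <- matrix(0, 1, 1)
  kmb$K[1, 1] <- 0.05             # >> 0.5*0.5/(2*10) = 0.0125
  kmb$populations <- "p1"
  pb <- simulate_null("poisson-binomial", individuals = list(p1 = a),
                      n_loci = 20000, seed = 6)
  vo <- simulate_null("mvn-variance-only", k_model = kmb, n_loci = 20000,
                      seed = 7)
  expect_lt(var(pb$freqs[, 1]), var(vo$freqs[, 1]))
})

test_that("FDR thresholds follow the ratio definition, monotonised toward the tail", {
  # point mass beyond the null maximum gets the 1% class
  nul <- runif(5000)
  obs <- c(runif(900), rep(1.5, 100))
  th <- fdr_thresholds(obs, nul, "high")
  expect_false(any(is.na(th)))
  expect_true(all(fdr_thresholds(obs, nul, "high")[["1%"]] <= 1.5))
  cls <- c(rep(NA, 0), clinedrift:::fdr_class(obs, th, "high"))
  expect_true(all(cls[obs == 1.5] == 1))
  # ratio-based: doubling L with the same distributions leaves thresholds be
  th2 <- fdr_thresholds(rep(obs, 2), nul, "high")
  expect_equal(th[["5%"]], th2[["5%"]])
  # low tail mirrors the high tail
  thl <- fdr_thresholds(-obs, -nul, "low")
  expect_equal(thl[["5%"]], -th[["5%"]])
  # observed drawn from the null itself: (almost) nothing passes 10%
  set.seed(8)
  same <- rnorm(5000)
  th3 <- fdr_thresholds(same, rnorm(20000), "high")
  n_pass <- if (is.na(th3[["10%"]])) 0 else sum(same >= th3[["10%"]])
  expect_lte(n_pass, 5)
  expect_error(fdr_thresholds(numeric(0), nul), "non-empty")
})

test_that("outlier classification nests FDR classes and flags shared outliers only when both zones agree", {
  obs <- list(N = c(0.9, 0.8, 0.2, 0.5), S = c(0.95, 0.4, 0.1, 0.5))
  mk <- function(t1, t5, t10, dir = "high") {
    x <- c("1%" = t1, "5%" = t5, "10%" = t10)
    attr(x, "direction") <- dir
    x
  }
  th <- list(
    N = list(high = mk(0.85, 0.75, 0.7), low = mk(0.05, 0.1, 0.15, "low")),
    S = list(high = mk(0.9, 0.85, 0.8), low = mk(0.05, 0.12, 0.2, "low")))
  res <- classify_outliers(obs, th)
  # SNP 1 beyond 1% in both -> shared, class 1/1
  expect_equal(res$fdr_high_N[1], 1L)
  expect_equal(res$fdr_high_S[1], 1L)
  expect_true(res$shared_high[1])
  # SNP 2 high in N only -> not shared
  expect_equal(res$fdr_high_N[2], 5L)
  expect_true(is.na(res$fdr_high_S[2]))
  expect_false(res$shared_high[2])
  # SNP 3 misses the N low-tail threshold -> not a shared low outlier
  expect_false(res$shared_low[3])
  expect_equal(res$fdr_low_S[3], 5L)
  # classes nest: 1% implies 5% implies 10% by construction of thresholds
  expect_true(all(is.na(res$fdr_high_N) | res$fdr_high_N %in% c(1, 5, 10)))
})

test_that("region merging matches midpoint windows, the 10kb rule and an interval-union oracle", {
  # two significant SNPs 5kb apart merge into one region
  snps <- data.frame(chrom = "chr1", pos = c(10000, 15000, 40000))
  r <- merge_outlier_regions(snps, c(10L, 5L, NA), direction = "high-A")
  expect_equal(nrow(r), 1)
  expect_equal(r$min_fdr, 5L)
  expect_equal(r$n_snps, 2L)
  # windows separated by >= 10kb stay apart
  snps2 <- data.frame(chrom = "chr1",
                      pos = c(10000, 12000, 23000, 25000))
  r2 <- merge_outlier_regions(snps2, c(10L, NA, NA, 10L))
  expect_equal(nrow(r2), 2)
  # chain of SNPs at 8kb gaps merges into a single region matching a
  # brute-force union of midpoint windows
  pos <- seq(10000, 90000, by = 8000)
  snps3 <- data.frame(chrom = "chr1", pos = pos)
  r3 <- merge_outlier_regions(snps3, rep(10L, length(pos)))
  expect_equal(nrow(r3), 1)
  mid <- (pos[-1] + pos[-length(pos)]) / 2
  lo <- floor(pos[1] - (mid[1] - pos[1]))
  hi <- ceiling(pos[length(pos)] + pos[length(pos)] - mid[length(mid)])
  expect_equal(c(r3$start, r3$end), c(lo, hi))
})

test_that("gene overlap respects half-open coordinates and equals a quadratic oracle", {
  regions <- region_table(c("chr1", "chr1", "chr2"),
                          c(100, 500, 0), c(200, 900, 50),
                          "high-A", c(10L, 1L, 5L), "N,S", 1L)
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                      start = c(150, 200, 10, 50),
                      end = c(160, 300, 20, 80),
                      name = paste0("g", 1:4))
  hits <- overlap_regions_genes(regions, genes)
  expect_true("g1" %in% hits$gene)          # inside
  expect_false("g2" %in% hits$gene)         # abuts region end (half-open)
  expect_true("g3" %in% hits$gene)
  expect_false("g4" %in% hits$gene)         # starts at region end
  expect_equal(hits$min_fdr[hits$gene == "g1"], 10L)
  # random fixture vs brute-force all-pairs overlap
  set.seed(23)
  rs <- sort(sample.int(1e5, 20))
  regions2 <- region_table("chr1", rs, rs + sample.int(5000, 20),
                           "low-A", 10L, "S", 1L)
  gs <- sort(sample.int(1e5, 30))
  genes2 <- data.frame(chrom = "chr1", start = gs,
                       end = gs + sample.int(3000, 30),
                       name = paste0("G", 1:30))
  hits2 <- overlap_regions_genes(regions2, genes2)
  oracle <- vapply(seq_len(30), function(i)
    any(genes2$start[i] < regions2$end & regions2$start < genes2$end[i]),
    TRUE)
  expect_setequal(hits2$gene, genes2$name[oracle])
  # chromosome names not in the layout error out
  layout <- fixture_layout()
  badg <- data.frame(chrom = "chrQ", start = 1, end = 10, name = "x")
  expect_error(overlap_regions_genes(regions2, badg, layout), "chrQ")
})

test_that("group correlation contrasts pair by stratum and detect a planted cross-continent block", {
  groups <- c("lowA_S", "lowA_S", "highA_S", "highA_S", "lowA_N", "lowA_N")
  # identical, exchangeable strata: zero contrast, p = 1
  km <- fixture_kmodel(P = 6)
  km$corr <- matrix(0.3, 6, 6); diag(km$corr) <- 1
  res0 <- group_correlation_contrast(list(km, km, km), groups)
  expect_equal(res0$contrast, rep(0, 3), tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # planted block: lowA_S x lowA_N correlations elevated via a factor
  # model (base corr 0.3 everywhere; populations 1,2,5,6 share an extra
  # factor so their pairwise corr is 0.7)
  set.seed(24)
  mk_stratum <- function() {
    Lx <- 4000
    z0 <- rnorm(Lx); g1 <- rnorm(Lx); g2 <- rnorm(Lx)
    shared <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
    f <- vapply(1:6, function(i)
      0.5 + 0.1 * (sqrt(0.3) * z0 +
                     sqrt(0.4) * (if (shared[i]) g1 else g2) +
                     sqrt(0.3) * rnorm(Lx)), numeric(Lx))
    compute_K(f, rep(0.5, 6))
  }
  strata <- lapply(1:4, function(i) mk_stratum())
  res <- group_correlation_contrast(strata, groups)
  expect_gt(res$estimate, 0.2)
  expect_lt(res$p_value, 0.05)
  # permuting the stratum order leaves the paired statistic unchanged
  res_perm <- group_correlation_contrast(strata[c(3, 1, 4, 2)], groups)
  expect_equal(res_perm$estimate, res$estimate)
  expect_equal(res_perm$p_value, res$p_value)
  # a group with fewer than 2 populations errors
  expect_error(
    group_correlation_contrast(strata, c("lowA_S", "lowA_S", "highA_S",
                                         "highA_S", "highA_S", "lowA_N")),
    "< 2")
})
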