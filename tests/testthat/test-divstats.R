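test_that("read-count-weighted allele frequencies match the pooled-count oracle", {
  # two individuals: 3/3 alt and 0/3 alt -> 0.5, n = 4 haplotypes
  af <- pop_allele_freq(alt = matrix(c(3, 0), 1), depth = matrix(c(3, 3), 1))
  expect_equal(af$freq, 0.5)
  expect_equal(af$n, 4L)
  # a single covered individual is excluded
  af1 <- pop_allele_freq(alt = matrix(c(2, 0), 1), depth = matrix(c(4, 0), 1))
  expect_true(is.na(af1$freq))
  # random fixture vs direct pooled counts
  set.seed(31)
  depth <- matrix(rpois(200, 4), 20)
  alt <- matrix(rbinom(200, as.vector(depth), 0.3), 20)
  af2 <- pop_allele_freq(alt, depth)
  keep <- rowSums(depth > 0) >= 2
  expect_equal(af2$freq[keep],
               (rowSums(alt) / rowSums(depth))[keep])
  expect_equal(af2$n[keep], 2L * rowSums(depth > 0)[keep])
})

test_that("per-SNP heterozygosity applies the finite-sample correction", {
  expect_equal(snp_heterozygosity(0.5, 2), 1)
  expect_equal(snp_heterozygosity(0.5, 10), 0.5556, tolerance = 1e-4)
  expect_error(snp_heterozygosity(0.5, 1), "n >= 2")
})

test_that("genome-wide pi scales mean heterozygosity by SNP density", {
  # monomorphic set: pi = 0
  est0 <- pi_genomewide(rep(0, 50), rep(10, 50), mappable_sites = 1e6)
  expect_equal(est0$pi, 0)
  # direct arithmetic: 100 SNPs at p = 0.5, n = 10, over 1e6 sites
  est <- pi_genomewide(rep(0.5, 100), rep(10, 100), mappable_sites = 1e6)
  expect_equal(est$pi, (2 * 0.25 * 10 / 9) * 100 / 1e6)
  expect_error(pi_genomewide(0.5, 10, 0), "> 0")
})

test_that("block-bootstrap CI behaves on constant, iid and degenerate inputs", {
  layout <- fixture_layout(n_chrom = 2)
  set.seed(32)
  snps <- snp_table(layout, rep(c("chr1", "chr2"), each = 250),
                    c(sort(sample.int(1e6, 250)),
                      sort(sample.int(1e6, 250))))
  # constant statistic: zero-width CI
  cc <- block_bootstrap_ci(rep(3, 500), snps, block_cm = 1, n_boot = 100,
                           seed = 1)
  expect_equal(cc$ci, c(3, 3))
  # iid normal values: percentile CI close to the analytic mean CI
  v <- rnorm(500, 10, 2)
  bb <- block_bootstrap_ci(v, snps, block_cm = 1, n_boot = 2000, seed = 2)
  an <- t.test(v)$conf.int
  expect_equal(diff(bb$ci), diff(an), tolerance = 0.15)
  expect_equal(bb$estimate, mean(v))
  # basic CI also contains the estimate for these symmetric data
  bs <- block_bootstrap_ci(v, snps, block_cm = 1, n_boot = 500, seed = 3,
                           ci_type = "basic")
  expect_true(bs$ci[1] <= bs$estimate & bs$estimate <= bs$ci[2])
  # a single block is refused
  one <- data.frame(chrom = "chr1", cm = rep(0.1, 20))
  expect_error(block_bootstrap_ci(rnorm(20), one, block_cm = 10), "block")
})

test_that("predicted diversity from admixture weights follows the mixture closed form", {
  set.seed(33)
  pf <- cbind(A = runif(200), C = runif(200), M = runif(200))
  # w = (1,0,0): the A-panel heterozygosity pipeline
  pa <- predicted_pi_from_admixture(c(1, 0, 0), pf, 1e6)
  expect_equal(pa$pi, mean(2 * pf[, 1] * (1 - pf[, 1])) * 200 / 1e6)
  # two panels fixed for opposite alleles: maximal heterozygosity
  pf2 <- cbind(A = rep(1, 50), C = rep(0, 50), M = rep(0.5, 50))
  pb <- predicted_pi_from_admixture(c(0.5, 0.5, 0), pf2, 1e4)
  expect_equal(pb$pi, 0.5 * 50 / 1e4)
  # missing panel frequencies are skipped and counted
  pf3 <- pf; pf3[1:10, 2] <- NA
  pc <- predicted_pi_from_admixture(c(0.2, 0.5, 0.3), pf3, 1e6)
  expect_equal(pc$n_skipped, 10)
  expect_equal(pc$n_snps, 190)
  expect_error(predicted_pi_from_admixture(c(0.5, 0.2, 0.1), pf, 1e6),
               "sum to 1")
  # mixture of two diverged panels is more diverse than either panel
  pf4 <- cbind(A = rbeta(300, 0.4, 0.4), C = rbeta(300, 0.4, 0.4),
               M = rep(0.5, 300))
  pi_mix <- predicted_pi_from_admixture(c(0.5, 0.5, 0), pf4, 1e6)$pi
  pi_a <- predicted_pi_from_admixture(c(1, 0, 0), pf4, 1e6)$pi
  pi_c <- predicted_pi_from_admixture(c(0, 1, 0), pf4, 1e6)$pi
  expect_gte(pi_mix, max(pi_a, pi_c))
})

test_that("within-ancestry pi masks to homozygous tracts and applies the inclusion rule", {
  layout <- fixture_layout(n_chrom = 2)
  set.seed(34)
  snps <- snp_table(layout, rep(c("chr1", "chr2"), each = 100),
                    c(sort(sample.int(1e6, 100)),
                      sort(sample.int(1e6, 100))))
  n_ind <- 6
  depth <- matrix(rpois(200 * n_ind, 5) + 1, 200)
  alt <- matrix(rbinom(200 * n_ind, as.vector(depth), 0.4), 200)
  # population with zero focal ancestry: unavailable
  post0 <- matrix(0, n_ind, 200)
  e0 <- within_ancestry_pi(alt, depth, post0, snps, 1e6,
                           min_blocks = 2, min_chroms = 2)
  expect_false(e0$available)
  expect_true(is.na(e0$pi))
  # everyone homozygous everywhere: equals the genome-wide estimate
  post1 <- matrix(1, n_ind, 200)
  e1 <- within_ancestry_pi(alt, depth, post1, snps, 1e6,
                           min_blocks = 2, min_chroms = 2)
  af <- pop_allele_freq(alt, depth)
  eg <- pi_genomewide(af$freq, af$n, 1e6)
  expect_equal(e1$pi, eg$pi)
  # random mosaic equals a direct computation on the masked truth
  post <- matrix(runif(n_ind * 200), n_ind, 200)
  e2 <- within_ancestry_pi(alt, depth, post, snps, 1e6,
                           min_blocks = 2, min_chroms = 2)
  mask <- t(post > 0.8)
  dm <- depth * mask; am <- alt * mask
  keep <- rowSums(dm > 0) >= 2
  het <- snp_heterozygosity((rowSums(am) / rowSums(dm))[keep],
                            (2 * rowSums(dm > 0))[keep])
  expect_equal(e2$pi, mean(het) * sum(keep) / 1e6)
  # inclusion rule at full scale marks the small genome unavailable
  e3 <- within_ancestry_pi(alt, depth, post1, snps, 1e6)
  expect_false(e3$available)
  expect_match(e3$reason, "blocks")
})

test_that("Hudson F_ST matches closed forms and is label-swap invariant", {
  expect_equal(hudson_fst(1, 0, 10, 10), 1)
  expect_lt(abs(hudson_fst(0.5, 0.5, 1000, 1000)), 0.01)
  # direct evaluation of the estimator: (0.36 - 2*0.16/9) / 0.68
  expect_equal(hudson_fst(0.8, 0.2, 10, 10),
               (0.36 - 2 * 0.8 * 0.2 / 9) / 0.68)
  expect_equal(hudson_fst(0.8, 0.2, 10, 10), 0.4772, tolerance = 1e-3)
  # both fixed for the same allele: undefined
  expect_true(is.na(hudson_fst(0, 0, 10, 10)))
  expect_true(is.na(hudson_fst(0.5, 0.5, 2, 10)))
  set.seed(35)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(hudson_fst(p1, p2, 20, 14),
               hudson_fst(1 - p1, 1 - p2, 20, 14))
})

test_that("sliding F_ST windows average per-SNP values and drop thin windows", {
  snps <- data.frame(chrom = "chr1",
                     pos = as.integer(seq(1000, 49000, by = 1000)))
  n <- nrow(snps)
  set.seed(36)
  p1 <- runif(n, 0.6, 1); p2 <- runif(n, 0, 0.4)
  fw <- hudson_fst_windows(p1, p2, rep(20, n), rep(20, n), snps,
                           window = 50000, step = 50000, min_snps = 10)
  # the single covering window averages all per-SNP values
  full <- fw[fw$start == 0, ]
  expect_equal(full$fst, mean(hudson_fst(p1, p2, 20, 20)))
  expect_equal(full$n_snps, n)
  # raising min_snps above the SNP count drops every window
  none <- hudson_fst_windows(p1, p2, rep(20, n), rep(20, n), snps,
                             window = 5000, step = 1000, min_snps = 10)
  expect_true(all(none$n_snps >= 10))
})

test_that("AIM discovery applies coverage and frequency-difference filters with polarisation", {
  pf <- rbind(c(1.0, 0.0, 0.02),    # A-AIM
              c(0.96, 0.02, 0.10),  # A-M gap 0.86: rejected
              c(0.02, 0.98, 1.00),  # A-AIM (A far from both C and M)
              c(0.01, 0.98, 0.02))  # C-AIM, polarised (already high)
  colnames(pf) <- c("A", "C", "M")
  pn <- matrix(10, 4, 3, dimnames = list(NULL, colnames(pf)))
  aims <- discover_aims(pf, pn)
  expect_equal(aims$snp, c(1L, 3L, 4L))
  expect_equal(aims$focal, c("A", "A", "C"))
  # polarisation: focal frequency is the high one
  expect_true(all(aims$freq_A[aims$focal == "A"] > 0.95))
  expect_true(all(aims$freq_C[aims$focal == "C"] > 0.95))
  # low-coverage panels suppress discovery
  pn2 <- pn; pn2[1, 2] <- 4
  expect_equal(nrow(discover_aims(pf[1, , drop = FALSE],
                                  pn2[1, , drop = FALSE])), 0)
  # a flipped A-AIM is polarised so A carries the high-frequency allele
  pf3 <- matrix(c(0.01, 0.99, 0.98), 1,
                dimnames = list(NULL, c("A", "C", "M")))
  a3 <- discover_aims(pf3, pn[1, , drop = FALSE])
  expect_equal(a3$focal, "A")
  expect_gt(a3$freq_A, 0.95)
  # random panels vs brute-force filter replay
  set.seed(37)
  pfr <- cbind(A = runif(300), C = runif(300), M = runif(300))
  pnr <- matrix(sample(3:12, 900, TRUE), 300,
                dimnames = list(NULL, colnames(pfr)))
  got <- discover_aims(pfr, pnr)
  oracle <- 0L
  for (i in seq_len(300)) for (j in 1:3) {
    o <- setdiff(1:3, j)
    if (all(pnr[i, ] >= 5) &&
        abs(pfr[i, j] - pfr[i, o[1]]) > 0.95 &&
        abs(pfr[i, j] - pfr[i, o[2]]) > 0.95) oracle <- oracle + 1L
  }
  expect_equal(nrow(got), oracle)
})
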