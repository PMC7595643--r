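#' Read-count-weighted population allele frequency
#'
#' A simple unbiased population allele frequency based on the weighted
#' average of observed read counts across individuals: the pooled
#' alternate-read fraction. Sites where fewer than two individuals have
#' coverage are excluded (frequency `NA`); `n` counts 2 x individuals
#' with data at the site.
#'
#' @param alt sites x individuals matrix of alternate-allele read counts.
#' @param depth sites x individuals matrix of total read depth.
#' @param min_ind minimum individuals with coverage (default 2).
#' @return data.frame with `freq` and `n` (haplotypes with data) per site.
#' @export
pop_allele_freq <- function(alt, depth, min_ind = 2) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  stopifnot(all(dim(alt) == dim(depth)), all(depth >= 0), all(alt <= depth))
  n_ind <- rowSums(depth > 0)
  tot <- rowSums(depth)
  freq <- ifelse(n_ind >= min_ind & tot > 0, rowSums(alt) / tot, NA_real_)
  data.frame(freq = freq, n = ifelse(is.na(freq), NA_integer_, 2L * n_ind))
}

#' Per-SNP heterozygosity with finite-sample correction
#'
#' `2 p (1 - p) * n / (n - 1)` where `n` is the number of haplotypes with
#' data at the site.
#'
#' @param p allele frequency.
#' @param n haplotypes with data (>= 2).
#' @return per-SNP heterozygosity.
#' @export
snp_heterozygosity <- function(p, n) {
  if (any(n[!is.na(n)] < 2)) stop("finite-sample correction needs n >= 2")
  2 * p * (1 - p) * n / (n - 1)
}

#' Genome-wide nucleotide diversity per bp
#'
#' Mean per-SNP heterozygosity (with n/(n-1) finite-sample correction)
#' scaled by the density of included SNPs among all mappable sites:
#' `pi = mean(het) * n_included / mappable_sites`.
#'
#' @param freq,n per-SNP allele frequency and haplotype count (sites with
#'   `NA` frequency are excluded).
#' @param mappable_sites total mappable sites in the genome (> 0).
#' @param scope label (default "genomewide").
#' @param population label.
#' @return object of class `diversity_estimate`: list with `population`,
#'   `scope`, `pi`, `mean_het`, `n_snps`, `mappable_sites`, `ci` (NA until
#'   filled by a bootstrap), `available`.
#' @export
pi_genomewide <- function(freq, n, mappable_sites, scope = "genomewide",
                          population = NA_character_) {
  if (mappable_sites <= 0) stop("mappable_sites must be > 0")
  keep <- !is.na(freq)
  het <- snp_heterozygosity(freq[keep], n[keep])
  structure(list(population = population, scope = scope,
                 pi = mean(het) * sum(keep) / mappable_sites,
                 mean_het = mean(het), n_snps = sum(keep),
                 mappable_sites = mappable_sites,
                 ci = c(NA_real_, NA_real_), available = TRUE),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("diversity_estimate [%s, %s]: unavailable (%s)\n",
                x$population, x$scope, x$reason))
  } else {
    cat(sprintf(
      "diversity_estimate [%s, %s]: pi = %.3g per bp (%d SNPs)%s\n",
      x$population, x$scope, x$pi, x$n_snps,
      if (all(is.finite(x$ci)))
        sprintf(", 95%% CI [%.3g, %.3g]", x$ci[1], x$ci[2]) else ""))
  }
  invisible(x)
}

#' Block-bootstrap confidence interval for a per-SNP statistic
#'
#' Divides the genome into contiguous genetic-distance blocks
#' (`block_cm` cM, per chromosome), resamples blocks with replacement and
#' recomputes the statistic on each replicate. `ci_type = "percentile"`
#' (the diversity default) returns the empirical 2.5/97.5% quantiles;
#' `ci_type = "basic"` (the enrichment default) returns
#' `[2*theta_hat - q_0.975, 2*theta_hat - q_0.025]`.
#'
#' @param values per-SNP statistic values (NA allowed: dropped).
#' @param snps data.frame with `chrom` and `cm` aligned to `values`.
#' @param block_cm block size in cM (default 1).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param ci_type `"percentile"` or `"basic"`.
#' @param statistic function applied to the concatenated resampled values
#'   (default `mean`).
#' @return list with `estimate`, `ci` (length 2), `n_blocks`, `n_boot`.
#' @export
block_bootstrap_ci <- function(values, snps, block_cm = 1, n_boot = 10000,
                               seed = 1, ci_type = c("percentile", "basic"),
                               statistic = mean) {
  ci_type <- match.arg(ci_type)
  stopifnot(length(values) == nrow(snps))
  keep <- !is.na(values)
  values <- values[keep]
  block <- paste(snps$chrom[keep], floor(snps$cm[keep] / block_cm))
  block <- match(block, unique(block))
  B <- max(block)
  if (B < 2) stop("only one block; use smaller blocks (block_cm)")
  est <- statistic(values)
  blk <- split(values, block)
  identical_stat <- identical(statistic, mean)
  if (identical_stat) {
    bsum <- vapply(blk, sum, 0)
    bn <- vapply(blk, length, 0L)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(r) {
    w <- tabulate(sample.int(B, B, replace = TRUE), nbins = B)
    if (identical_stat) sum(w * bsum) / sum(w * bn)
    else statistic(unlist(blk[rep(seq_len(B), w)], use.names = FALSE))
  }, 0)
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  ci <- if (ci_type == "percentile") q else c(2 * est - q[2], 2 * est - q[1])
  list(estimate = est, ci = ci, n_blocks = B, n_boot = n_boot)
}

#' Predicted diversity from admixture proportions and panel frequencies
#'
#' The expected allele frequency in an admixed population is the mixture
#' of reference-panel frequencies weighted by the population's admixture
#' fractions, `p_bar = sum_k w_k p_k`; predicted heterozygosity is
#' `2 p_bar (1 - p_bar)` and is scaled to per-bp diversity via the same
#' SNP-density pipeline. SNPs missing a panel frequency are skipped and
#' counted.
#'
#' @param weights admixture fractions (named or ordered as the panel
#'   columns; must sum to 1 within 1e-6).
#' @param panel_freqs sites x panels matrix of reference allele
#'   frequencies.
#' @param mappable_sites total mappable sites.
#' @param population label.
#' @return a `diversity_estimate` with `scope = "predicted"` and
#'   `n_skipped` recorded.
#' @export
predicted_pi_from_admixture <- function(weights, panel_freqs,
                                        mappable_sites,
                                        population = NA_character_) {
  panel_freqs <- as.matrix(panel_freqs)
  stopifnot(length(weights) == ncol(panel_freqs))
  if (abs(sum(weights) - 1) > 1e-6) stop("admixture weights must sum to 1")
  ok <- stats::complete.cases(panel_freqs)
  pbar <- as.numeric(panel_freqs[ok, , drop = FALSE] %*% weights)
  het <- 2 * pbar * (1 - pbar)
  out <- structure(list(population = population, scope = "predicted",
                        pi = mean(het) * sum(ok) / mappable_sites,
                        mean_het = mean(het), n_snps = sum(ok),
                        mappable_sites = mappable_sites,
                        ci = c(NA_real_, NA_real_), available = TRUE,
                        n_skipped = sum(!ok)),
                   class = "diversity_estimate")
  out
}

#' Extract high-confidence homozygous-ancestry masks per individual
#'
#' Consecutive SNPs with posterior probability > `post_min` for the same
#' homozygous ancestry state form high-confidence tracts; the returned
#' mask flags the SNP-individual combinations inside such tracts.
#'
#' @param posterior individuals x sites matrix of posterior probabilities
#'   for the homozygous state of the focal ancestry.
#' @param post_min posterior cutoff (default 0.8).
#' @return logical individuals x sites mask.
#' @export
homozygous_tract_mask <- function(posterior, post_min = 0.8) {
  as.matrix(posterior) > post_min
}

#' Within-ancestry nucleotide diversity
#'
#' Restricts the allele-frequency and heterozygosity pipeline to data
#' inside high-confidence homozygous tracts of the focal ancestry, then
#' applies a block/chromosome inclusion rule: the population estimate is
#' reported only when data cover at least `min_blocks` distinct
#' `block_cm`-cM blocks spread across at least `min_chroms` chromosomes;
#' otherwise the estimate is marked unavailable (a value, not an error).
#'
#' @param alt,depth sites x individuals read-count matrices.
#' @param posterior individuals x sites posterior probabilities of the
#'   homozygous focal-ancestry state (note the transposed orientation,
#'   matching per-individual HMM output).
#' @param snps data.frame with `chrom`, `cm` per site.
#' @param mappable_sites total mappable sites.
#' @param post_min posterior cutoff for tract membership.
#' @param min_blocks,min_chroms,block_cm inclusion rule.
#' @param scope,population labels.
#' @return a `diversity_estimate`; when unavailable, `pi` is `NA` and
#'   `reason` explains why.
#' @export
within_ancestry_pi <- function(alt, depth, posterior, snps, mappable_sites,
                               post_min = 0.8, min_blocks = 75,
                               min_chroms = 15, block_cm = 1,
                               scope = "within-A",
                               population = NA_character_) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  mask <- t(homozygous_tract_mask(posterior, post_min)) # sites x individuals
  stopifnot(all(dim(mask) == dim(depth)))
  depth_m <- depth * mask
  alt_m <- alt * mask
  af <- pop_allele_freq(alt_m, depth_m)
  has_data <- !is.na(af$freq)
  blocks <- unique(paste(snps$chrom[has_data],
                         floor(snps$cm[has_data] / block_cm)))
  chroms <- unique(snps$chrom[has_data])
  if (length(blocks) < min_blocks || length(chroms) < min_chroms) {
    return(structure(list(population = population, scope = scope,
                          pi = NA_real_, mean_het = NA_real_,
                          n_snps = sum(has_data),
                          mappable_sites = mappable_sites,
                          ci = c(NA_real_, NA_real_), available = FALSE,
                          reason = sprintf(
                            "%d blocks on %d chromosomes (need >= %d on >= %d)",
                            length(blocks), length(chroms), min_blocks,
                            min_chroms)),
                     class = "diversity_estimate"))
  }
  out <- pi_genomewide(af$freq, af$n, mappable_sites, scope = scope,
                       population = population)
  out$n_blocks <- length(blocks)
  out
}

#' Hudson's per-SNP F_ST estimator
#'
#' `F_hat = [(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#'          [p1(1-p2) + p2(1-p1)]`
#' with `n` the haplotype counts. SNPs where both groups are fixed for
#' the same allele (zero denominator) or `n < 4` haplotypes in either
#' group return `NA`.
#'
#' @param p1,p2 allele frequencies in the two groups.
#' @param n1,n2 haplotype counts.
#' @return per-SNP F_ST (may be slightly negative).
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  out <- num / den
  out[den == 0 | n1 < 4 | n2 < 4 | is.na(p1) | is.na(p2)] <- NA_real_
  out
}

#' Sliding-window mean Hudson F_ST
#'
#' Averages per-SNP Hudson F_ST within sliding windows (default 50 kb
#' stepping 1 kb); windows with fewer than `min_snps` usable SNPs are
#' dropped.
#'
#' @param p1,p2,n1,n2 per-SNP frequencies and haplotype counts for the
#'   two groups.
#' @param snps data.frame with `chrom`, `pos` aligned to the SNPs.
#' @param window,step window size and step in bp.
#' @param min_snps minimum usable SNPs per window (default 10).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `fst`, `n_snps`.
#' @export
hudson_fst_windows <- function(p1, p2, n1, n2, snps, window = 50000,
                               step = 1000, min_snps = 10) {
  fst <- hudson_fst(p1, p2, n1, n2)
  out <- list()
  for (ch in unique(snps$chrom)) {
    sel <- which(snps$chrom == ch & !is.na(fst))
    if (!length(sel)) next
    pos <- snps$pos[sel]
    ord <- order(pos)
    pos <- pos[ord]
    f <- fst[sel][ord]
    cs <- cumsum(f)
    starts <- seq(from = step * floor((min(pos) - window) / step),
                  to = max(pos), by = step)
    starts <- starts[starts + window >= min(pos) & starts <= max(pos)]
    starts <- unique(pmax(starts, 0))
    lo <- findInterval(starts, pos, left.open = TRUE) + 1L  # first pos > start
    hi <- findInterval(starts + window, pos)                # last pos <= end
    n <- hi - lo + 1L
    keep <- n >= min_snps
    if (!any(keep)) next
    sums <- cs[hi[keep]] - ifelse(lo[keep] > 1, cs[lo[keep] - 1L], 0)
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = starts[keep], end = starts[keep] + window,
      fst = sums / n[keep], n_snps = n[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), fst = numeric(),
                      n_snps = integer()))
  do.call(rbind, out)
}

#' Discover ancestry-informative markers (AIMs)
#'
#' A SNP is an AIM for a focal ancestry when every reference panel has
#' data for at least `min_ind` individuals and the focal panel's allele
#' frequency differs from both other panels by more than `min_diff`.
#' Alleles are polarised so the focal panel carries the high-frequency
#' variant.
#'
#' @param panel_freqs sites x 3 matrix of panel allele frequencies
#'   (columns named by ancestry, e.g. A, C, M).
#' @param panel_n sites x 3 matrix of individuals with data per panel.
#' @param min_ind minimum individuals per panel (default 5).
#' @param min_diff minimum frequency difference, exclusive (default 0.95).
#' @return data.frame: `snp`, `focal`, one frequency column per panel
#'   (polarised), plus per-panel individual counts; one row per (SNP,
#'   focal ancestry) passing the filters.
#' @export
discover_aims <- function(panel_freqs, panel_n, min_ind = 5,
                          min_diff = 0.95) {
  panel_freqs <- as.matrix(panel_freqs)
  panel_n <- as.matrix(panel_n)
  stopifnot(ncol(panel_freqs) == 3, all(dim(panel_freqs) == dim(panel_n)))
  ks <- colnames(panel_freqs)
  if (is.null(ks)) ks <- c("A", "C", "M")
  cov_ok <- rowSums(panel_n >= min_ind) == 3
  rows <- list()
  for (j in seq_len(3)) {
    others <- setdiff(seq_len(3), j)
    d1 <- abs(panel_freqs[, j] - panel_freqs[, others[1]])
    d2 <- abs(panel_freqs[, j] - panel_freqs[, others[2]])
    hit <- which(cov_ok & d1 > min_diff & d2 > min_diff &
                   stats::complete.cases(panel_freqs))
    if (!length(hit)) next
    f <- panel_freqs[hit, , drop = FALSE]
    flip <- f[, j] < 0.5   # polarise: focal carries high-frequency allele
    f[flip, ] <- 1 - f[flip, ]
    df <- data.frame(snp = hit, focal = ks[j], stringsAsFactors = FALSE)
    for (m in seq_len(3)) df[[paste0("freq_", ks[m])]] <- f[, m]
    for (m in seq_len(3)) df[[paste0("n_", ks[m])]] <- panel_n[hit, m]
    rows[[length(rows) + 1]] <- df
  }
  if (!length(rows)) {
    df <- data.frame(snp = integer(), focal = character())
    for (m in seq_len(3)) df[[paste0("freq_", ks[m])]] <- numeric()
    for (m in seq_len(3)) df[[paste0("n_", ks[m])]] <- integer()
    return(df)
  }
  out <- do.call(rbind, rows)
  out[order(out$snp), , drop = FALSE]
}
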