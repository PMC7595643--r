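#' Null distribution of per-SNP cline slopes under drift
#'
#' Simulates neutral ancestry frequencies under the full MVN drift model
#' and refits the per-SNP logistic cline (M = 1) to each simulated locus,
#' returning the distribution of absolute slopes expected without
#' selection. Unfittable simulated loci (flat frequencies) are counted and
#' excluded with a warning.
#'
#' @param k_model a `k_model` for the continent whose sampling spans the
#'   full cline.
#' @param latitudes population predictor values aligned to the K model.
#' @param n_loci number of simulated loci.
#' @param seed RNG seed.
#' @param n_starts random starts per per-SNP fit.
#' @return numeric vector of null `|b|` values, with the number of
#'   excluded loci in `attr(, "n_excluded")`.
#' @export
null_slope_distribution <- function(k_model, latitudes, n_loci = 100000,
                                    seed = 1, n_starts = 4) {
  ens <- simulate_null("mvn-full", k_model = k_model, n_loci = n_loci,
                       seed = seed)
  fits <- fit_snp_clines(ens$freqs, latitudes, M = 1, n_starts = n_starts,
                         seed = seed + 1L)
  drop <- !fits$converged
  if (any(drop))
    warning(sum(drop), " simulated loci unfittable; excluded")
  out <- abs(fits$b[!drop])
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Steepness FDR thresholds and flags for observed cline slopes
#'
#' Applies the simulation-calibrated FDR machinery ([fdr_thresholds()]) to
#' absolute cline slopes, upper tail.
#'
#' @param observed_b observed per-SNP slopes (sign ignored).
#' @param null_b null `|b|` sample, e.g. from
#'   [null_slope_distribution()].
#' @param target FDR target (default 5%).
#' @return list with `threshold` (NA if no threshold attains the target)
#'   and `flagged` (logical per observed SNP).
#' @export
steepness_fdr <- function(observed_b, null_b, target = 0.05) {
  th <- fdr_thresholds(abs(observed_b), abs(null_b), direction = "high",
                       targets = target)
  t1 <- th[[1]]
  flagged <- if (is.na(t1)) rep(FALSE, length(observed_b)) else
    abs(observed_b) >= t1
  list(threshold = t1, flagged = flagged)
}

#' Flag the empirical top fraction of steepest clines
#'
#' Exactly `ceiling(frac * L)` SNPs are flagged; ties in `|b|` are broken
#' by position order (earlier SNPs first).
#'
#' @param b per-SNP slopes.
#' @param frac fraction to flag (default 5%).
#' @return logical vector.
#' @export
top_slope_flags <- function(b, frac = 0.05) {
  L <- length(b)
  k <- ceiling(frac * L)
  ord <- order(-abs(b), seq_len(L))
  flags <- rep(FALSE, L)
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Recombination-rate bin enrichment of steep clines via block bootstrap
#'
#' Assigns SNPs to recombination-rate bins (by the containing map-window
#' rate) and to contiguous genetic-distance blocks (`block_cm` cM per
#' chromosome, final partial block kept). Per bootstrap replicate, blocks
#' are resampled with replacement and the per-bin mean `|b|` and per-bin
#' proportion of the (fixed, original) top-steepest SNPs are recomputed.
#' Confidence intervals are basic bootstrap intervals,
#' `[2*theta_hat - q_0.975, 2*theta_hat - q_0.025]`. `delta_b` is the
#' lowest-bin minus highest-bin mean `|b|`.
#'
#' @param b per-SNP slopes.
#' @param snps data.frame with `chrom`, `pos`, `cm`, `recomb_rate` (e.g.
#'   from [snp_table()]).
#' @param bin_edges recombination-rate bin edges (cM/Mb); the default
#'   computes genome quintiles of the per-SNP rates. First bin closed.
#' @param block_cm block size in cM (default 0.2).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param top_frac empirical steep fraction (default 5%).
#' @param recompute_top recompute the top-steep cutoff inside each
#'   replicate instead of holding the original membership fixed
#'   (default FALSE).
#' @return object of class `enrichment_result`: list with `bin_edges`,
#'   `bins` (data.frame: bin, n_snps, prop_top, prop_ci_low/high, mean_b,
#'   mean_b_ci_low/high), `delta_b`, `delta_b_ci`, `n_boot`, `block_cm`.
#' @export
enrichment_block_bootstrap <- function(b, snps, bin_edges = NULL,
                                       block_cm = 0.2, n_boot = 10000,
                                       seed = 1, top_frac = 0.05,
                                       recompute_top = FALSE) {
  stopifnot(length(b) == nrow(snps))
  ab <- abs(b)
  if (is.null(bin_edges))
    bin_edges <- unique(stats::quantile(snps$recomb_rate,
                                        probs = seq(0, 1, 0.2), names = FALSE))
  nb <- length(bin_edges) - 1
  bin <- cut(snps$recomb_rate, breaks = bin_edges, include.lowest = TRUE,
             labels = FALSE)
  if (any(is.na(bin))) stop("SNP recombination rate outside bin edges")
  empty <- setdiff(seq_len(nb), unique(bin))
  if (length(empty)) warning("empty recombination bin(s): ",
                             paste(empty, collapse = ", "),
                             "; CIs missing there")
  block <- paste(snps$chrom, floor(snps$cm / block_cm))
  block <- match(block, unique(block))
  B <- max(block)
  top <- top_slope_flags(b, top_frac)

  # per-block per-bin sufficient statistics
  key <- (block - 1L) * nb + bin
  dim_bb <- B * nb
  sum_b <- numeric(dim_bb); cnt <- numeric(dim_bb); cnt_top <- numeric(dim_bb)
  agg <- function(v) {
    z <- numeric(dim_bb)
    t <- tapply(v, key, sum)
    z[as.integer(names(t))] <- t
    z
  }
  sum_b <- agg(ab); cnt <- agg(rep(1, length(ab))); cnt_top <- agg(top)
  Msum <- matrix(sum_b, nrow = B, byrow = TRUE)
  Mcnt <- matrix(cnt, nrow = B, byrow = TRUE)
  Mtop <- matrix(cnt_top, nrow = B, byrow = TRUE)
  if (recompute_top) {
    # need per-block slope lists to re-rank; keep index list per block
    blk_idx <- split(seq_along(ab), block)
  }

  point_mean <- colSums(Msum) / colSums(Mcnt)
  point_prop <- colSums(Mtop) / colSums(Mcnt)
  point_delta <- point_mean[1] - point_mean[nb]

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  boot_mean <- matrix(NA_real_, n_boot, nb)
  boot_prop <- matrix(NA_real_, n_boot, nb)
  for (r in seq_len(n_boot)) {
    w <- tabulate(sample.int(B, B, replace = TRUE), nbins = B)
    cs <- as.numeric(w %*% Mcnt)
    boot_mean[r, ] <- as.numeric(w %*% Msum) / cs
    if (recompute_top) {
      idx <- unlist(blk_idx[rep(seq_len(B), w)], use.names = FALSE)
      tf <- top_slope_flags(ab[idx], top_frac)
      bb <- bin[idx]
      boot_prop[r, ] <- vapply(seq_len(nb), function(j)
        mean(tf[bb == j]), 0)
    } else {
      boot_prop[r, ] <- as.numeric(w %*% Mtop) / cs
    }
  }
  # basic bootstrap interval, widened if needed so it always contains the
  # point estimate (possible to lose it when the resampling distribution
  # is strongly skewed for a sparse bin)
  basic_ci <- function(est, reps) {
    q <- stats::quantile(reps, c(0.975, 0.025), na.rm = TRUE, names = FALSE)
    c(min(2 * est - q[1], est), max(2 * est - q[2], est))
  }
  bins <- data.frame(bin = seq_len(nb),
                     rate_low = bin_edges[-(nb + 1)],
                     rate_high = bin_edges[-1],
                     n_snps = as.integer(colSums(Mcnt)),
                     prop_top = point_prop, mean_b = point_mean)
  ci_p <- t(vapply(seq_len(nb), function(j)
    if (bins$n_snps[j] == 0) c(NA, NA) else
      basic_ci(point_prop[j], boot_prop[, j]), numeric(2)))
  ci_m <- t(vapply(seq_len(nb), function(j)
    if (bins$n_snps[j] == 0) c(NA, NA) else
      basic_ci(point_mean[j], boot_mean[, j]), numeric(2)))
  bins$prop_ci_low <- ci_p[, 1]; bins$prop_ci_high <- ci_p[, 2]
  bins$mean_b_ci_low <- ci_m[, 1]; bins$mean_b_ci_high <- ci_m[, 2]
  delta_reps <- boot_mean[, 1] - boot_mean[, nb]
  structure(list(bin_edges = bin_edges, bins = bins,
                 delta_b = point_delta,
                 delta_b_ci = basic_ci(point_delta, delta_reps),
                 n_boot = n_boot, block_cm = block_cm,
                 n_blocks = B, top_frac = top_frac),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d bins, %d blocks (%.2g cM), %d bootstraps\n",
    nrow(x$bins), x$n_blocks, x$block_cm, x$n_boot))
  print(x$bins, digits = 3)
  cat(sprintf("delta |b| (lowest - highest bin): %.4g [%.4g, %.4g]\n",
              x$delta_b, x$delta_b_ci[1], x$delta_b_ci[2]))
  invisible(x)
}
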