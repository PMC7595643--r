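#' Empirical population ancestry variance-covariance (K) matrix
#'
#' For populations i and j with genome-wide mean A-ancestry proportions
#' `alpha_i`, `alpha_j` and locus-wise ancestry frequencies `anc_il`,
#' `anc_jl`, the ancestry covariance over L loci is
#' `K[i,j] = (1/L) * sum_l (anc_il - alpha_i) * (anc_jl - alpha_j)`.
#' The deviations are taken from the genome-wide means supplied in
#' `alpha`, not from the column means of `freqs`.
#'
#' @param freqs loci x populations matrix of A-ancestry frequencies.
#' @param alpha genome-wide mean ancestry proportion per population
#'   (aligned to columns of `freqs`).
#' @return object of class `k_model`: list with `populations`, `alpha`,
#'   `K`, `corr` (correlation matrix, `NA` where a population has zero
#'   variance) and `L`.
#' @export
compute_K <- function(freqs, alpha) {
  freqs <- as.matrix(freqs)
  L <- nrow(freqs)
  if (L < 1) stop("need at least 1 locus")
  stopifnot(length(alpha) == ncol(freqs), all(alpha >= 0 & alpha <= 1))
  D <- sweep(freqs, 2, alpha)
  K <- crossprod(D) / L
  v <- diag(K)
  corr <- K / sqrt(outer(v, v))
  if (any(v == 0)) {
    message("population(s) with zero ancestry variance: correlations NA")
    corr[v == 0, ] <- NA
    corr[, v == 0] <- NA
  }
  pops <- colnames(freqs)
  if (is.null(pops)) pops <- paste0("pop", seq_along(alpha))
  structure(list(populations = pops, alpha = as.numeric(alpha), K = K,
                 corr = corr, L = L),
            class = "k_model")
}

#' @export
print.k_model <- function(x, ...) {
  cat("k_model:", length(x$populations), "populations, L =", x$L, "loci\n")
  cat("  mean diagonal variance:", signif(mean(diag(x$K)), 4), "\n")
  invisible(x)
}

chol_with_ridge <- function(K, ridge = 1e-10) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) {
    warning("K not positive definite; adding ridge ", ridge,
            " to the diagonal")
    R <- tryCatch(chol(K + diag(ridge, nrow(K))), error = function(e) NULL)
    if (is.null(R))
      stop("K not positive semi-definite even after ridge repair; ",
           "increase the ridge or rebuild K")
  }
  R
}

#' Simulate neutral ancestry frequencies under one of three null models
#'
#' * `"poisson-binomial"`: per locus and population, each individual
#'   contributes 2 alleles drawn Binomial(2, a_i) where `a_i` is the
#'   individual's genome-wide ancestry proportion; the population
#'   frequency is the mean allele dosage / 2. Accounts for sampling
#'   variance only.
#' * `"mvn-variance-only"`: independent normal per population with the K
#'   diagonal as variance (drift within populations, no covariance).
#' * `"mvn-full"`: A ancestry ~ MVN(alpha, K), capturing shared drift.
#'
#' MVN draws are truncated to `[0, 1]` (each out-of-range population
#' frequency is set to the bound) and the truncated fractions reported.
#'
#' @param model one of `"poisson-binomial"`, `"mvn-variance-only"`,
#'   `"mvn-full"`.
#' @param k_model a `k_model` (required for the MVN variants).
#' @param individuals for the Poisson-binomial model: a list, one element
#'   per population, of per-individual genome-wide ancestry proportions.
#' @param n_loci number of independent loci to simulate.
#' @param seed RNG seed; draws are deterministic given the seed.
#' @return object of class `null_ensemble`: list with `model`, `freqs`
#'   (n_loci x P matrix), `seed`, `trunc_low`, `trunc_high`.
#' @export
simulate_null <- function(model = c("mvn-full", "mvn-variance-only",
                                    "poisson-binomial"),
                          k_model = NULL, individuals = NULL,
                          n_loci = 100000, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_loci >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  trunc_low <- trunc_high <- 0
  if (model == "poisson-binomial") {
    if (is.null(individuals))
      stop("poisson-binomial model needs per-individual proportions")
    f <- vapply(individuals, function(a) {
      n <- length(a)
      dose <- matrix(stats::rbinom(n_loci * n, 2, rep(a, each = n_loci)),
                     nrow = n_loci)
      rowMeans(dose) / 2
    }, numeric(n_loci))
    pops <- names(individuals)
  } else {
    if (is.null(k_model)) stop(model, " model needs a k_model")
    P <- length(k_model$alpha)
    if (model == "mvn-variance-only") {
      sd_p <- sqrt(pmax(diag(k_model$K), 0))
      f <- matrix(stats::rnorm(n_loci * P, mean = rep(k_model$alpha,
                                                      each = n_loci),
                               sd = rep(sd_p, each = n_loci)),
                  nrow = n_loci)
    } else {
      R <- chol_with_ridge(k_model$K)
      Z <- matrix(stats::rnorm(n_loci * P), nrow = n_loci)
      f <- Z %*% R + matrix(k_model$alpha, n_loci, P, byrow = TRUE)
    }
    trunc_low <- mean(f < 0)
    trunc_high <- mean(f > 1)
    f[f < 0] <- 0
    f[f > 1] <- 1
    pops <- k_model$populations
  }
  colnames(f) <- pops
  structure(list(model = model, freqs = f, n_loci = n_loci, seed = seed,
                 trunc_low = trunc_low, trunc_high = trunc_high),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "null_ensemble [%s]: %d loci x %d populations (truncated: %.2g%% low, %.2g%% high)\n",
    x$model, x$n_loci, ncol(x$freqs), 100 * x$trunc_low,
    100 * x$trunc_high))
  invisible(x)
}

#' Simulation-calibrated FDR thresholds for one-tailed outlier tests
#'
#' For a candidate threshold t (scanned over the observed order
#' statistics), the estimated false-discovery rate is
#' `FDR(t) = (P_null(stat beyond t) * L_obs) / #observed beyond t`.
#' The curve is monotonised by taking, at each candidate, the minimum FDR
#' achievable at any threshold at least as extreme, and the least extreme
#' candidate whose monotonised FDR is at or below each target is returned.
#'
#' @param observed observed per-SNP statistics.
#' @param null_stat null-ensemble statistics (same scale).
#' @param direction `"high"` (upper tail) or `"low"` (lower tail).
#' @param targets FDR targets as fractions (default 1%, 5%, 10%).
#' @return named numeric vector of thresholds (NA = no threshold attains
#'   the target, meaning zero outliers at that level), with the per-
#'   candidate FDR curve in `attr(, "fdr_curve")`.
#' @export
fdr_thresholds <- function(observed, null_stat,
                           direction = c("high", "low"),
                           targets = c(0.01, 0.05, 0.10)) {
  direction <- match.arg(direction)
  if (!length(observed) || !length(null_stat))
    stop("observed and null distributions must be non-empty")
  sgn <- if (direction == "high") 1 else -1
  obs <- sort(sgn * observed, decreasing = TRUE)   # most extreme first
  nul_asc <- sort(sgn * null_stat)
  L <- length(obs)
  n_obs_beyond <- seq_len(L)
  # count null >= t for each observed candidate t
  n_null_beyond <- length(nul_asc) -
    findInterval(obs, nul_asc, left.open = TRUE)
  p_null <- n_null_beyond / length(nul_asc)
  fdr <- pmin(p_null * L / n_obs_beyond, 1)
  # monotonise (q-value style): the FDR attributed to threshold t is the
  # minimum estimated FDR over thresholds no more extreme than t, which
  # enforces a non-increasing curve toward the tail without letting the
  # extreme tail's zero counts leak into the bulk
  fdr_mono <- rev(cummin(rev(fdr)))
  out <- vapply(targets, function(tg) {
    ok <- which(fdr_mono <= tg)
    if (!length(ok)) NA_real_ else sgn * obs[max(ok)]
  }, 0)
  names(out) <- paste0(round(targets * 100), "%")
  attr(out, "fdr_curve") <- data.frame(threshold = sgn * obs, fdr = fdr,
                                       fdr_mono = fdr_mono)
  attr(out, "direction") <- direction
  out
}

fdr_class <- function(stat, thresholds, direction) {
  sgn <- if (direction == "high") 1 else -1
  cls <- rep(NA_integer_, length(stat))
  lev <- c("10%" = 10L, "5%" = 5L, "1%" = 1L)
  for (nm in names(lev)) {
    t <- thresholds[[nm]]
    if (!is.null(t) && !is.na(t)) cls[sgn * stat >= sgn * t] <- lev[[nm]]
  }
  cls
}

#' Classify per-SNP ancestry outliers and shared outliers across zones
#'
#' Each continent/direction combination is tested one-tailed against its
#' own simulation-calibrated thresholds; a SNP is a shared outlier when it
#' meets the 10% FDR in the same direction in both continents.
#'
#' @param obs named list of observed per-SNP continental mean frequencies,
#'   e.g. `list(N = ..., S = ...)` (unweighted means over populations).
#' @param thresholds nested list `thresholds[[continent]][[direction]]` of
#'   [fdr_thresholds()] outputs, directions `"high"` and `"low"`.
#' @return data.frame of class `outlier_result`: per SNP the continental
#'   means, FDR classes (`fdr_high_<cont>`, `fdr_low_<cont>`; percent, NA
#'   = not significant) and `shared_high` / `shared_low` flags.
#' @export
classify_outliers <- function(obs, thresholds) {
  conts <- names(obs)
  L <- length(obs[[1]])
  out <- data.frame(snp = seq_len(L))
  for (ct in conts) {
    out[[paste0("mean_", ct)]] <- obs[[ct]]
    for (dir in c("high", "low")) {
      th <- thresholds[[ct]][[dir]]
      out[[paste0("fdr_", dir, "_", ct)]] <-
        if (is.null(th)) NA_integer_ else fdr_class(obs[[ct]], th, dir)
    }
  }
  if (length(conts) >= 2) {
    sig <- function(dir) {
      Reduce(`&`, lapply(conts, function(ct)
        !is.na(out[[paste0("fdr_", dir, "_", ct)]])))
    }
    out$shared_high <- sig("high")
    out$shared_low <- sig("low")
  }
  class(out) <- c("outlier_result", "data.frame")
  out
}

#' Continental mean ancestry frequency per SNP
#'
#' @param freqs loci x populations matrix.
#' @param continent per-column continent labels.
#' @param weights optional per-population sample sizes for a weighted
#'   mean; the default is the unweighted mean over populations.
#' @return named list of per-SNP mean vectors, one per continent.
#' @export
continental_means <- function(freqs, continent, weights = NULL) {
  freqs <- as.matrix(freqs)
  stopifnot(ncol(freqs) == length(continent))
  sapply(unique(continent), function(ct) {
    cols <- which(continent == ct)
    if (is.null(weights)) rowMeans(freqs[, cols, drop = FALSE])
    else as.numeric(freqs[, cols, drop = FALSE] %*% weights[cols] /
                      sum(weights[cols]))
  }, simplify = FALSE)
}

#' Merge significant SNPs into contiguous outlier regions
#'
#' Each significant SNP expands to its midpoint-bounded window (ancestry
#' calls apply to the short genomic window spanning midway to the next
#' call); windows separated by less than `max_gap` bp merge into one
#' region labelled with the lowest (best) FDR class inside.
#'
#' @param snps data.frame with `chrom` and `pos`, sorted by position
#'   within chromosome (all scanned SNPs, not only significant ones).
#' @param fdr per-SNP FDR class in percent (NA = not significant).
#' @param direction label stored on the regions (e.g. `"high-A"`).
#' @param max_gap merge windows closer than this many bp (default 10 kb).
#' @param continents label stored on the regions.
#' @return a `region_table` (0-based half-open coordinates), non-
#'   overlapping within the scan.
#' @export
merge_outlier_regions <- function(snps, fdr, direction = "high-A",
                                  max_gap = 10000, continents = NA) {
  stopifnot(nrow(snps) == length(fdr))
  res <- list()
  for (ch in unique(snps$chrom)) {
    sel <- snps$chrom == ch
    pos <- snps$pos[sel]
    if (is.unsorted(pos)) stop("SNPs must be sorted by position")
    f <- fdr[sel]
    n <- length(pos)
    # midpoint-bounded windows (0-based half-open); chromosome-end SNPs
    # extend by half the gap to their single neighbour
    mid <- if (n > 1) (pos[-n] + pos[-1]) / 2 else numeric(0)
    w_start <- floor(c(if (n > 1) pos[1] - (mid[1] - pos[1]) else pos[1] - 1,
                       mid))
    w_end <- ceiling(c(mid, if (n > 1) pos[n] + (pos[n] - mid[n - 1])
                       else pos[n]))
    w_start <- pmax(w_start, 0)
    sig <- which(!is.na(f))
    if (!length(sig)) next
    s <- w_start[sig]; e <- w_end[sig]; cls <- f[sig]
    brk <- which(s[-1] - e[-length(e)] >= max_gap)
    grp <- cumsum(c(1, seq_along(s)[-1] %in% (brk + 1)))
    for (g in unique(grp)) {
      i <- grp == g
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = min(s[i]), end = max(e[i]),
        direction = direction, min_fdr = min(cls[i]),
        continents = continents, n_snps = sum(i),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(region_table(character(), integer(), integer(), character()))
  r <- do.call(rbind, res)
  region_table(r$chrom, r$start, r$end, r$direction, r$min_fdr,
               r$continents, r$n_snps)
}

#' Overlap outlier regions with gene/QTL intervals
#'
#' Reports genes with at least 1 bp overlap (half-open coordinates) with
#' any region, with the per-gene minimum FDR and supporting continents.
#'
#' @param regions a `region_table`.
#' @param genes data.frame with `chrom`, `start`, `end`, `name` (BED-style
#'   0-based half-open, e.g. from [read_genes_bed()]).
#' @param layout optional `genome_layout`; when given, chromosome names in
#'   `regions` or `genes` that are absent from the layout raise an error
#'   listing the unmatched names.
#' @return data.frame: `gene`, `chrom`, `start`, `end`, `min_fdr`,
#'   `continents`, `n_regions`.
#' @export
overlap_regions_genes <- function(regions, genes, layout = NULL) {
  if (!is.null(layout)) {
    known <- layout$chromosomes$chrom
    bad <- setdiff(unique(c(regions$chrom, genes$chrom)), known)
    if (length(bad))
      stop("chromosome name(s) not in layout: ", paste(bad, collapse = ", "))
  }
  if (!nrow(regions) || !nrow(genes))
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      min_fdr = integer(), continents = character(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  hits_list <- list()
  for (ch in intersect(unique(genes$chrom), unique(regions$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    # half-open intervals: convert to closed integer ranges [start, end-1]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(g$start + 1L, g$end),
      IRanges::IRanges(r$start + 1L, r$end))
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    for (u in unique(qi)) {
      rs <- si[qi == u]
      hits_list[[length(hits_list) + 1]] <- data.frame(
        gene = g$name[u], chrom = ch, start = g$start[u], end = g$end[u],
        min_fdr = min(r$min_fdr[rs]),
        continents = paste(sort(unique(stats::na.omit(r$continents[rs]))),
                           collapse = ","),
        n_regions = length(rs), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits_list))
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      min_fdr = integer(), continents = character(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  do.call(rbind, hits_list)
}

#' Contrast mean ancestry correlations between population groups
#'
#' Summarises a list of stratum-wise K models (e.g. one per chromosome or
#' recombination-rate quintile) into the mean pairwise ancestry
#' correlation per comparison type, then tests a paired contrast between
#' two comparison types across strata with a two-sided paired t-test.
#' Typical use: do low-A South American populations correlate more with
#' low-A North American populations than with high-A South American ones?
#'
#' @param k_models list of `k_model` objects, one per stratum, all with
#'   identical population ordering.
#' @param groups character vector assigning each population to a group
#'   (e.g. `"lowA_S"`, `"highA_S"`, `"lowA_N"`), derived from the fitted
#'   genome-wide cline center. Every group needs at least 2 populations
#'   present in cross-group pairs (groups of 1 are allowed only within
#'   pairs across groups; a comparison type with no pairs errors).
#' @param comparison character(2): the two comparison types to contrast,
#'   each `"groupA:groupB"`; the contrast is mean(corr type1) -
#'   mean(corr type2) per stratum.
#' @return list with `per_stratum` (data.frame of mean correlations per
#'   comparison type), `contrast` (per-stratum differences), `estimate`,
#'   `conf_int`, `p_value`.
#' @export
group_correlation_contrast <- function(k_models, groups,
                                       comparison = c("lowA_S:lowA_N",
                                                      "lowA_S:highA_S")) {
  stopifnot(length(k_models) >= 2, length(comparison) == 2)
  P <- length(groups)
  pair_type <- function(g1, g2) paste(sort(c(g1, g2)), collapse = ":")
  want <- vapply(strsplit(comparison, ":"), function(p)
    pair_type(p[1], p[2]), "")
  for (w in strsplit(comparison, ":")) {
    n1 <- sum(groups == w[1]); n2 <- sum(groups == w[2])
    if (n1 < 2 || n2 < 2)
      stop("group with < 2 populations: ",
           paste(c(w[1], w[2])[c(n1, n2) < 2], collapse = ", "))
  }
  ij <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  types <- mapply(function(a, b) pair_type(groups[a], groups[b]),
                  ij[, 1], ij[, 2])
  per <- t(vapply(k_models, function(km) {
    stopifnot(inherits(km, "k_model"), length(km$populations) == P)
    cc <- km$corr[ij]
    tapply(cc, types, mean, na.rm = TRUE)[unique(types)]
  }, stats::setNames(numeric(length(unique(types))), unique(types))))
  per <- as.data.frame(per)
  if (!all(want %in% names(per)))
    stop("comparison type(s) absent: ",
         paste(setdiff(want, names(per)), collapse = ", "))
  d <- per[[want[1]]] - per[[want[2]]]
  tt <- if (stats::sd(d) == 0) {
    list(estimate = mean(d), conf.int = c(mean(d), mean(d)), p.value = 1)
  } else stats::t.test(d)
  list(per_stratum = per, contrast = d,
       estimate = unname(if (is.list(tt)) tt$estimate else tt$estimate),
       conf_int = as.numeric(tt$conf.int), p_value = tt$p.value)
}
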