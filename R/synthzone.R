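#' Configuration for the synthetic hybrid-zone generator
#'
#' Defaults emulate the sampling design of the replicated honey-bee
#' hybrid zones: a 12-population northern transect sampled over ~6
#' degrees of latitude, a 21-population southern transect spanning the
#' full cline, 278 current-study bees (8-9 per population) plus 35
#' previously published northern bees, logistic genome-wide clines with
#' asymptotic maximum 0.84 and centers 32.72 (N) / 32.26 (S) degrees
#' absolute latitude, a wing-length model of -0.72 mm per unit A ancestry
#' with 9 damaged (missing) wings, and A/C/M reference panels of 17/9/9
#' individuals.
#'
#' @param n_loci number of simulated loci.
#' @param lat_N,lat_S population latitudes (degrees; southern negative).
#' @param n_per_pop_N,n_per_pop_S per-population sample sizes.
#' @param include_prior include the 6 extra previously published northern
#'   populations (35 bees, no wings).
#' @param M,b_N,b_S,c_N,c_S genome-wide cline parameters (absolute
#'   latitude units).
#' @param var_scale diagonal of the construction K is
#'   `var_scale * alpha * (1 - alpha)`. The default 0.03 makes the
#'   [0,1] truncation fractions of the full-MVN drift null on this
#'   design (~5% at the lower bound, <0.1% at the upper) match the
#'   scale reported for the emulated study.
#' @param decay_deg exponential distance-decay length (degrees latitude)
#'   for within-continent ancestry correlation.
#' @param cross_block extra correlation coupling low-A populations
#'   (`alpha < M/2`) across continents.
#' @param ind_sd sd of individual genome-wide proportions around the
#'   population mean.
#' @param wing_intercept,wing_slope,wing_sd wing model (mm; mm per unit
#'   A; residual sd). The residual sd default 0.30 mm is derived from the
#'   emulated study conditions: with a slope of -0.72 mm per unit A and
#'   the design's ancestry spread (sd ~0.28 across both transects),
#'   `sd_resid = |slope| * sd_A * sqrt((1 - R2) / R2)` with R2 = 0.31
#'   gives 0.30 mm, so genome-wide ancestry explains ~31% of wing
#'   variance.
#' @param n_damaged current-study bees with missing wings.
#' @param n_feral southern bees flagged as sampled beside a feral nest.
#' @param outlier_n,outlier_shift,outlier_direction planted outlier loci:
#'   count, ancestry-frequency shift applied to every population's mean,
#'   and direction (`"high"` adds, `"low"` subtracts). Shifted means are
#'   clamped to `[0, 1]` so frequencies stay in range before truncation.
#' @param panel_sizes individuals per A/C/M reference panel.
#' @param panel_F per-ancestry Balding-Nichols divergence parameter for
#'   reference allele frequencies.
#' @param n_chrom,chrom_mb,map_window_bp genome: chromosome count,
#'   length (Mb) and map window size.
#' @param rate_shape,rate_scale Gamma parameters for per-window
#'   recombination rates (cM/Mb); the defaults give a right-skewed
#'   distribution with mean ~27 cM/Mb, honey-bee-like.
#' @param mean_depth,error_rate,depth_var_factor read-count model.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_loci = 10000,
                         lat_N = seq(32.7, 38.5, length.out = 12),
                         lat_S = -seq(28.0, 36.0, length.out = 21),
                         n_per_pop_N = rep(8L, 12),
                         n_per_pop_S = c(rep(9L, 14), rep(8L, 7)),
                         include_prior = TRUE,
                         M = 0.84, b_N = -0.8, b_S = -0.8,
                         c_N = 32.72, c_S = 32.26,
                         var_scale = 0.03, decay_deg = 3,
                         cross_block = 0.1,
                         ind_sd = 0.05,
                         wing_intercept = 9.0, wing_slope = -0.72,
                         wing_sd = 0.30, n_damaged = 9L, n_feral = 8L,
                         outlier_n = 0L, outlier_shift = 0.3,
                         outlier_direction = "high",
                         panel_sizes = c(A = 17L, C = 9L, M = 9L),
                         panel_F = c(A = 0.35, C = 0.35, M = 0.35),
                         n_chrom = 16L, chrom_mb = 2, map_window_bp = 1e5,
                         rate_shape = 2, rate_scale = 13.5,
                         mean_depth = 5, error_rate = 0.01,
                         depth_var_factor = 3) {
  stopifnot(M > 0, M <= 1, n_loci >= 1, var_scale >= 0, ind_sd >= 0,
            length(lat_N) == length(n_per_pop_N),
            length(lat_S) == length(n_per_pop_S))
  stopifnot(outlier_shift > 0, outlier_shift <= 1,
            outlier_direction %in% c("high", "low"))
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' Construct a generative population ancestry covariance matrix
#'
#' Diagonal `var_scale * alpha * (1 - alpha)`; within-continent
#' correlation decays exponentially with latitudinal distance
#' (`exp(-d / decay_deg)`); low-A populations (`alpha < M/2`) on
#' different continents get an extra `cross_block` correlation, emulating
#' the observed coupling of the climatically similar cline ends.
#'
#' @param alpha per-population mean A proportions.
#' @param latitude per-population latitudes (signed degrees).
#' @param continent per-population continent labels.
#' @param var_scale,decay_deg,cross_block see [synth_config()].
#' @param M cline maximum used for the low-A grouping.
#' @return P x P covariance matrix (checked positive definite; if the
#'   construction fails the check, an error advises a ridge).
#' @export
construct_K <- function(alpha, latitude, continent, var_scale = 0.03,
                        decay_deg = 3, cross_block = 0.1, M = 0.84) {
  P <- length(alpha)
  v <- var_scale * alpha * (1 - alpha)
  same <- outer(continent, continent, "==")
  d <- abs(outer(abs(latitude), abs(latitude), "-"))
  corr <- ifelse(same, exp(-d / decay_deg), 0)
  low <- alpha < M / 2
  cross_low <- outer(low, low, "&") & !same
  corr[cross_low] <- cross_block
  diag(corr) <- 1
  K <- corr * sqrt(outer(v, v))
  # tiny diagonal jitter keeps the construction strictly positive
  # definite when the cross-continent block sits on the PSD boundary
  diag(K) <- diag(K) + 1e-8 * mean(v)
  ok <- tryCatch({ chol(K + diag(1e-12, P)); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    stop("constructed K is not positive semi-definite; reduce ",
         "cross_block or add a diagonal ridge")
  K
}

#' Simulate a two-continent hybrid-zone dataset with known truth
#'
#' Population mean ancestry follows the configured logistic clines;
#' latent locus-wise population frequencies are drawn from
#' MVN(alpha, K) and truncated to `[0, 1]`; planted outlier loci shift
#' the mean at chosen loci; individual genome-wide proportions are
#' normal around the population mean (clamped); per-locus individual
#' A-allele dosages are Binomial(2, latent population frequency); wing
#' lengths follow the linear ancestry model with gaussian noise. The
#' returned ancestry-frequency matrix holds the realised per-population
#' mean dosages/2 (what a local-ancestry HMM would estimate from the
#' sampled bees); the latent MVN frequencies live in the truth record.
#' Everything is deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return list of class `synthetic_dataset`: `populations`,
#'   `individuals`, `layout`, `snps`, `freqs` (L x P realised),
#'   `dosages` (individuals x L), `panel_freqs`, `panel_n`,
#'   `mappable_sites`, and `truth` (cline parameters, K, alpha, latent
#'   frequencies, outlier loci, phenotype coefficients, seed).
#' @export
simulate_hybrid_zones <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  cfg <- config

  # genome layout with gamma-distributed window recombination rates
  chroms <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                       length = as.integer(cfg$chrom_mb * 1e6))
  wins <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(i) {
    s <- seq(0, chroms$length[i] - 1, by = cfg$map_window_bp)
    data.frame(chrom = chroms$chrom[i], start = s,
               end = pmin(s + cfg$map_window_bp, chroms$length[i]),
               rate = stats::rgamma(length(s), shape = cfg$rate_shape,
                                    scale = cfg$rate_scale))
  }))
  layout <- genome_layout(chroms, wins)

  # SNP positions uniform over the genome
  L <- cfg$n_loci
  chr_idx <- sample.int(cfg$n_chrom, L, replace = TRUE,
                        prob = chroms$length)
  pos <- 1L + floor(stats::runif(L) * (chroms$length[chr_idx] - 1))
  snps <- snp_table(layout, chroms$chrom[chr_idx], pos)

  # populations
  mk_pops <- function(lat, n, continent, dataset, lon) {
    data.frame(population = sprintf("%s%02d", continent, seq_along(lat)),
               continent = continent, latitude = lat, longitude = lon,
               n = n, dataset = dataset, stringsAsFactors = FALSE)
  }
  pops <- rbind(
    mk_pops(cfg$lat_N, cfg$n_per_pop_N, "N", "current", -121),
    mk_pops(cfg$lat_S, cfg$n_per_pop_S, "S", "current", -60))
  if (cfg$include_prior) {
    prior <- mk_pops(seq(33.3, 38.5, length.out = 6),
                     c(6L, 6L, 6L, 6L, 6L, 5L), "N", "prior", -119)
    prior$population <- sprintf("Nprior%02d", 1:6)
    pops <- rbind(pops, prior)
  }
  P <- nrow(pops)
  b_of <- ifelse(pops$continent == "N", cfg$b_N, cfg$b_S)
  c_of <- ifelse(pops$continent == "N", cfg$c_N, cfg$c_S)
  alpha <- logistic_cline(abs(pops$latitude), cfg$M, b_of, c_of)
  pops$alpha <- alpha

  K <- construct_K(alpha, pops$latitude, pops$continent, cfg$var_scale,
                   cfg$decay_deg, cfg$cross_block, cfg$M)

  # planted outlier loci: shift every population's mean at chosen loci
  outlier_loci <- integer(0)
  mu <- matrix(alpha, L, P, byrow = TRUE)
  if (cfg$outlier_n > 0) {
    outlier_loci <- sort(sample.int(L, cfg$outlier_n))
    sgn <- if (cfg$outlier_direction == "high") 1 else -1
    mu[outlier_loci, ] <- pmin(pmax(mu[outlier_loci, ] +
                                      sgn * cfg$outlier_shift, 0), 1)
  }

  # latent MVN frequencies, truncated; a zero K collapses exactly onto mu
  latent <- if (max(abs(K)) == 0) mu else
    matrix(stats::rnorm(L * P), L, P) %*% chol_with_ridge(K) + mu
  latent[latent < 0] <- 0
  latent[latent > 1] <- 1
  colnames(latent) <- pops$population

  # individuals
  ind <- do.call(rbind, lapply(seq_len(P), function(i) {
    n <- pops$n[i]
    A <- pmin(pmax(stats::rnorm(n, alpha[i], cfg$ind_sd), 0), 1)
    wC <- pmin(pmax(stats::rnorm(n, 0.65, 0.1), 0), 1)
    data.frame(id = sprintf("%s_b%02d", pops$population[i], seq_len(n)),
               population = pops$population[i],
               continent = pops$continent[i],
               latitude = pops$latitude[i],
               longitude = pops$longitude[i],
               A = A, C = (1 - A) * wC, M = (1 - A) * (1 - wC),
               dataset = pops$dataset[i], stringsAsFactors = FALSE)
  }))
  N_ind <- nrow(ind)
  ind$wing_mm <- NA_real_
  cur <- which(ind$dataset == "current")
  ind$wing_mm[cur] <- cfg$wing_intercept + cfg$wing_slope * ind$A[cur] +
    stats::rnorm(length(cur), 0, cfg$wing_sd)
  if (cfg$n_damaged > 0)
    ind$wing_mm[sample(cur, cfg$n_damaged)] <- NA_real_
  ind$feral <- FALSE
  s_idx <- which(ind$continent == "S")
  if (cfg$n_feral > 0)
    ind$feral[sample(s_idx, cfg$n_feral)] <- TRUE

  # per-individual local-ancestry dosages ~ Binomial(2, latent pop freq)
  pop_of <- match(ind$population, pops$population)
  dosages <- matrix(stats::rbinom(N_ind * L, 2,
                                  prob = t(latent[, pop_of])),
                    nrow = N_ind)
  rownames(dosages) <- ind$id

  # realised ancestry frequency matrix (what the HMM would estimate)
  freqs <- t(rowsum(dosages, group = pops$population[pop_of]) /
               (2 * as.vector(table(pops$population[pop_of])[
                 sort(unique(pops$population[pop_of]))])))
  freqs <- freqs[, pops$population, drop = FALSE]

  # reference panels: Balding-Nichols around a shared ancestral frequency
  anc_p <- stats::runif(L, 0.05, 0.95)
  panel_freqs <- sapply(names(cfg$panel_F), function(k) {
    F <- cfg$panel_F[[k]]
    stats::rbeta(L, anc_p * (1 - F) / F, (1 - anc_p) * (1 - F) / F)
  })
  panel_n <- matrix(rep(cfg$panel_sizes, each = L), L,
                    dimnames = list(NULL, names(cfg$panel_sizes)))

  structure(list(
    populations = pops, individuals = ind, layout = layout, snps = snps,
    freqs = freqs, dosages = dosages, panel_freqs = panel_freqs,
    panel_n = panel_n,
    mappable_sites = sum(chroms$length),
    truth = list(M = cfg$M, b = c(N = cfg$b_N, S = cfg$b_S),
                 c = c(N = cfg$c_N, S = cfg$c_S), alpha = alpha,
                 K = K, latent_freqs = latent,
                 outlier_loci = outlier_loci,
                 outlier_direction = cfg$outlier_direction,
                 outlier_shift = cfg$outlier_shift,
                 wing_intercept = cfg$wing_intercept,
                 wing_slope = cfg$wing_slope, wing_sd = cfg$wing_sd,
                 seed = seed)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d populations (%d bees), %d loci, seed %d\n",
    nrow(x$populations), nrow(x$individuals), nrow(x$freqs),
    x$truth$seed))
  invisible(x)
}

#' Simulate low-coverage read counts from genotypes
#'
#' Site depth is negative-binomial with variance `var_factor` times the
#' mean; alternate reads are binomial in the allele dose perturbed by the
#' sequencing error rate (`q = (g/2)(1-e) + (1-g/2)e` for genotype `g`).
#'
#' @param genotypes vector or matrix of genotypes in {0, 1, 2}.
#' @param mean_depth mean site depth (> 0).
#' @param error_rate per-read error rate.
#' @param var_factor depth variance/mean ratio (> 1; default 3).
#' @param seed RNG seed.
#' @return list with `depth` and `alt`, same shape as `genotypes`.
#' @export
simulate_read_counts <- function(genotypes, mean_depth = 5,
                                 error_rate = 0.01, var_factor = 3,
                                 seed = 1) {
  g <- genotypes
  stopifnot(all(g %in% 0:2), mean_depth > 0,
            error_rate >= 0, error_rate <= 1)
  if (var_factor <= 1)
    stop("var_factor must exceed 1 for the negative-binomial ",
         "parameterisation (variance > mean)")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  n <- length(g)
  size <- mean_depth / (var_factor - 1)
  depth <- stats::rnbinom(n, size = size, mu = mean_depth)
  q <- (as.vector(g) / 2) * (1 - error_rate) +
    (1 - as.vector(g) / 2) * error_rate
  alt <- stats::rbinom(n, depth, q)
  dim(depth) <- dim(g)
  dim(alt) <- dim(g)
  list(depth = depth, alt = alt)
}

#' Write a synthetic dataset as the pipeline's TSV formats
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(dataset$populations, "populations.tsv"),
    w(dataset$individuals[, c("id", "population", "continent", "latitude",
                              "longitude", "A", "C", "M", "wing_mm",
                              "feral", "dataset")], "individuals.tsv"),
    w(cbind(dataset$snps[, c("chrom", "pos")],
            as.data.frame(dataset$freqs)), "ancestry_freqs.tsv"),
    w(dataset$snps, "snps.tsv"),
    w(do.call(rbind, lapply(dataset$layout$map, function(x)
      x[, c("chrom", "start", "end", "rate")])), "map.tsv"),
    w(dataset$layout$chromosomes, "chromosomes.tsv"))
  invisible(paths)
}
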