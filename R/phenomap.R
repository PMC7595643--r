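#' Linear model of wing length on genome-wide ancestry
#'
#' Ordinary least squares of wing length (mm) on the genome-wide A
#' ancestry proportion, optionally adding a continent main effect and an
#' A x continent interaction. Bees with missing wing lengths are excluded
#' and counted.
#'
#' @param individuals data.frame with `A`, `wing_mm` and (for the
#'   continent terms) `continent`.
#' @param with_continent_terms add a South-America main effect and
#'   interaction term (default FALSE).
#' @return list with `model` (the `lm` fit), `slope` (mm per unit A),
#'   `intercept`, `r2`, `n`, `p_slope`, `n_excluded`, and when continent
#'   terms are included `p_continent` and `p_interaction`.
#' @export
fit_wing_ancestry_lm <- function(individuals, with_continent_terms = FALSE) {
  stopifnot(all(c("A", "wing_mm") %in% names(individuals)))
  keep <- !is.na(individuals$wing_mm) & !is.na(individuals$A)
  n_excluded <- sum(!keep)
  d <- individuals[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 bees with measured wings")
  if (with_continent_terms) {
    stopifnot("continent" %in% names(d))
    d$continent <- factor(d$continent)
    fit <- stats::lm(wing_mm ~ A * continent, data = d)
  } else {
    fit <- stats::lm(wing_mm ~ A, data = d)
  }
  sm <- summary(fit)
  co <- stats::coef(sm)
  out <- list(model = fit, slope = co["A", "Estimate"],
              intercept = co["(Intercept)", "Estimate"],
              r2 = sm$r.squared, n = nrow(d),
              p_slope = co["A", "Pr(>|t|)"], n_excluded = n_excluded)
  if (with_continent_terms) {
    rn <- rownames(co)
    main <- grep("^continent", rn, value = TRUE)
    inter <- grep("^A:continent", rn, value = TRUE)
    out$p_continent <- if (length(main)) co[main[1], "Pr(>|t|)"] else NA
    out$p_interaction <- if (length(inter)) co[inter[1], "Pr(>|t|)"] else NA
  }
  out
}

#' Gaussian GLM of logit ancestry on latitude and feral-nest sampling
#'
#' Fits `logit(A) ~ |latitude| + feral` with gaussian errors, after
#' clamping A to `[eps, 1 - eps]` so the logit is finite. Used to check
#' whether bees collected next to feral nests are ancestry outliers for
#' their sampling location.
#'
#' @param individuals data.frame with `A`, `latitude` and logical/0-1
#'   `feral`.
#' @param eps clamp width (default 1e-3).
#' @return list with `model`, `coefficients` (data.frame) and `p_feral`.
#' @export
feral_nest_glm <- function(individuals, eps = 1e-3) {
  stopifnot(all(c("A", "latitude", "feral") %in% names(individuals)))
  feral <- as.logical(individuals$feral)
  if (length(unique(feral)) < 2)
    stop("feral flag is constant; cannot estimate its effect")
  a <- pmin(pmax(individuals$A, eps), 1 - eps)
  d <- data.frame(y = stats::qlogis(a),
                  abs_lat = abs(individuals$latitude), feral = feral)
  fit <- stats::glm(y ~ abs_lat + feral, data = d, family = stats::gaussian())
  co <- as.data.frame(stats::coef(summary(fit)))
  list(model = fit, coefficients = co,
       p_feral = co["feralTRUE", "Pr(>|t|)"])
}

#' Admixture mapping scan of a phenotype on local ancestry dosage
#'
#' Two-stage scan: wing length is first regressed on genome-wide A
#' ancestry; the residuals are then regressed on the A-ancestry allele
#' count (MAP dosage 0/1/2) at each SNP in turn, with a two-tailed test
#' per SNP. SNPs with monomorphic dosage get a missing p-value.
#'
#' @param individuals data.frame with `A` and `wing_mm` (missing wings
#'   excluded).
#' @param dosages individuals x SNPs matrix of A-ancestry allele counts
#'   aligned to `individuals` rows.
#' @return object of class `admixture_map_result`: data.frame with per-SNP
#'   `beta`, `t`, `p`, plus attributes `n` and `stage1` (the genome-wide
#'   model).
#' @export
admixture_map_scan <- function(individuals, dosages) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(individuals))
  keep <- !is.na(individuals$wing_mm) & !is.na(individuals$A)
  d <- individuals[keep, , drop = FALSE]
  X <- dosages[keep, , drop = FALSE]
  stage1 <- stats::lm(wing_mm ~ A, data = d)
  y <- stats::resid(stage1)
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  r <- ifelse(sxx > 0, sxy / sqrt(sxx * syy), NA_real_)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  out <- data.frame(snp = seq_len(ncol(X)), beta = beta, t = tval, p = p)
  attr(out, "n") <- n
  attr(out, "stage1") <- stage1
  class(out) <- c("admixture_map_result", "data.frame")
  out
}

#' Analytic genome-wide significance threshold for admixture mapping
#'
#' In admixture mapping the effective number of tests depends on how many
#' generations of recombination have broken up ancestry blocks. Treating
#' the per-SNP Z statistic along the genome as an Ornstein-Uhlenbeck
#' process whose autocorrelation decays at rate `g` per Morgan (`g` =
#' generations since admixture), the family-wise error rate of a
#' two-tailed scan at threshold `z` is approximated by the expected
#' number of boundary crossings,
#' `alpha(z) = m * [ C * 2*pnorm(-z) + 2 * g * G * z * dnorm(z) ]`,
#' with `C` chromosomes, `G` the total map length in Morgans and `m` the
#' number of parallel ancestry-dosage scans (`n_ancestries - 1`; the
#' default 2 corresponds to scanning a single focal ancestry). The
#' returned threshold is the two-tailed p-value `2*pnorm(-z*)` at the
#' `z*` solving `alpha(z*) = fwer`; it decreases as `g` or the map length
#' grows.
#'
#' @param g generations since admixture (> 0).
#' @param layout a `genome_layout` supplying chromosome count and total
#'   genetic map length.
#' @param n_ancestries number of ancestral populations (default 2:
#'   one focal-ancestry dosage scan).
#' @param fwer target family-wise error rate (default 0.05).
#' @return p-value threshold in (0, 1).
#' @export
admixture_threshold <- function(g, layout, n_ancestries = 2, fwer = 0.05) {
  stopifnot(g > 0, n_ancestries >= 2, fwer > 0, fwer < 1)
  G <- total_map_cm(layout) / 100   # Morgans
  if (G <= 0) stop("layout has non-positive total map length")
  C <- nrow(layout$chromosomes)
  m <- n_ancestries - 1
  alpha_of_z <- function(z)
    m * (C * 2 * stats::pnorm(-z) + 2 * g * G * z * stats::dnorm(z))
  root <- stats::uniroot(function(z) alpha_of_z(z) - fwer,
                         lower = 0.5, upper = 12, tol = 1e-12)$root
  2 * stats::pnorm(-root)
}

#' Honey-bee-like genome layout
#'
#' A 16-chromosome layout with physical lengths close to the honey bee
#' reference assembly (~220 Mb total) and a uniform recombination rate
#' (default 19 cM/Mb, the genome-wide average scale reported for honey
#' bees, giving a ~42 Morgan map).
#'
#' @param rate_cM_Mb uniform recombination rate (cM/Mb).
#' @param window_bp map window size (bp).
#' @return a `genome_layout`.
#' @export
honeybee_layout <- function(rate_cM_Mb = 19, window_bp = 5e6) {
  len_mb <- c(27.75, 16.09, 13.62, 13.40, 13.90, 17.79, 14.20, 12.72,
              12.40, 12.20, 16.17, 11.35, 11.17, 10.06, 9.53, 7.24)
  chroms <- data.frame(chrom = paste0("chr", seq_along(len_mb)),
                       length = as.integer(len_mb * 1e6))
  wins <- do.call(rbind, lapply(seq_along(len_mb), function(i) {
    s <- seq(0, chroms$length[i] - 1, by = window_bp)
    data.frame(chrom = chroms$chrom[i], start = s,
               end = pmin(s + window_bp, chroms$length[i]),
               rate = rate_cM_Mb)
  }))
  genome_layout(chroms, wins)
}
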