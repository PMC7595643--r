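#' Logistic cline prediction
#'
#' The cline model is `A(x) = M / (1 + exp(-b * (x - c)))`: `M` is the
#' asymptotic maximum ancestry proportion approaching the equator, `b` the
#' slope per predictor unit and `c` the cline center in predictor units.
#'
#' @param x predictor values (e.g. absolute latitude).
#' @param M,b,c cline parameters.
#' @return predicted ancestry proportions.
#' @export
logistic_cline <- function(x, M, b, c) M / (1 + exp(-b * (x - c)))

cline_rss <- function(par, x, A, M_fixed) {
  if (is.null(M_fixed)) {
    M <- par[3]
    if (M <= 0 || M > 1) return(1e10)
  } else M <- M_fixed
  sum((A - logistic_cline(x, M, par[1], par[2]))^2)
}

#' Fit a logistic cline by multi-start nonlinear least squares
#'
#' Minimises the residual sum of squares of the logistic cline over
#' `n_starts` random starting values (`b ~ Unif(-5, 5)`,
#' `c ~ Unif(min(x), max(x))`), returning the global best by RSS. AIC is
#' computed under gaussian errors as `n*log(RSS/n) + 2k`, counting the
#' error variance as a parameter (`k` = free cline parameters + 1).
#'
#' @param x predictor values (finite, at least 4 points, not constant).
#' @param A ancestry proportions in `[0, 1]`.
#' @param M either a fixed asymptotic maximum in `(0, 1]` or `"free"`.
#' @param n_starts number of random starts.
#' @param seed RNG seed for the starts.
#' @param predictor label stored in the fit.
#' @param c_bounds optional length-2 bounds for the center `c`; defaults to
#'   the observed predictor range widened by one range-width on each side.
#' @return object of class `cline_fit`: list with `predictor`, `M`, `b`,
#'   `c`, `width` (`= 4/|b|`), `rss`, `n`, `k`, `aic`, `n_starts`, `seed`,
#'   `converged`.
#' @export
fit_logistic_cline <- function(x, A, M = 0.84, n_starts = 100, seed = 1,
                               predictor = "x", c_bounds = NULL) {
  keep <- is.finite(x) & is.finite(A)
  x <- x[keep]; A <- A[keep]
  if (length(x) < 4) stop("need at least 4 points")
  if (any(A < 0 | A > 1)) stop("ancestry proportions must be in [0,1]")
  if (diff(range(x)) == 0) stop("degenerate predictor: all values equal")
  M_fixed <- if (identical(M, "free")) NULL else {
    stopifnot(is.numeric(M), M > 0, M <= 1)
    M
  }
  rng <- range(x)
  if (is.null(c_bounds)) c_bounds <- rng + c(-1, 1) * diff(rng)
  free <- if (is.null(M_fixed)) 3L else 2L
  lower <- c(-50, c_bounds[1], 1e-6)[seq_len(free)]
  upper <- c(50, c_bounds[2], 1)[seq_len(free)]

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  starts <- cbind(stats::runif(n_starts, -5, 5),
                  stats::runif(n_starts, rng[1], rng[2]),
                  stats::runif(n_starts, 0.4, 1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, seq_len(free)], cline_rss, x = x, A = A,
                   M_fixed = M_fixed, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(starts[s, seq_len(free)], cline_rss, x = x, A = A,
                     M_fixed = M_fixed, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000)),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(predictor = predictor, M = NA, b = NA, c = NA,
                          width = NA, rss = NA, n = length(x),
                          k = free + 1L, aic = NA, n_starts = n_starts,
                          seed = seed, converged = FALSE),
                     class = "cline_fit"))
  }
  # polish the winner
  pol <- tryCatch(
    stats::optim(best$par, cline_rss, x = x, A = A, M_fixed = M_fixed,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000)),
    error = function(e) best)
  if (pol$value < best$value) best <- pol
  b <- best$par[1]; cc <- best$par[2]
  Mhat <- if (is.null(M_fixed)) best$par[3] else M_fixed
  n <- length(x); k <- free + 1L
  rss <- best$value
  structure(list(predictor = predictor, M = Mhat, b = b, c = cc,
                 width = if (b != 0) 4 / abs(b) else Inf, rss = rss, n = n,
                 k = k, aic = n * log(rss / n) + 2 * k,
                 n_starts = n_starts, seed = seed, converged = TRUE),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "logistic cline fit [%s]: M = %.4g, b = %.4g, c = %.4g, width = %.4g\n",
    x$predictor, x$M, x$b, x$c, x$width))
  cat(sprintf("  rss = %.6g, n = %d, AIC = %.4g, converged = %s\n",
              x$rss, x$n, x$aic, x$converged))
  invisible(x)
}

#' Predict ancestry from a fitted cline
#' @param object a `cline_fit`.
#' @param newdata predictor values.
#' @param ... unused.
#' @export
predict.cline_fit <- function(object, newdata, ...) {
  logistic_cline(newdata, object$M, object$b, object$c)
}

#' Cline width from the logistic slope
#'
#' The width is the inverse of the steepest ancestry gradient at the cline
#' center, `4 / |b|`, in predictor units.
#'
#' @param b logistic slope (non-zero).
#' @return width in predictor units.
#' @export
cline_width <- function(b) {
  if (any(b == 0)) stop("flat cline (b = 0) has infinite width")
  4 / abs(b)
}

#' Geodesic (ellipsoidal) distance between coordinates, in km
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km (vectorised).
#' @export
geodesic_distance_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 360))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(as.numeric(lon1), n), rep_len(as.numeric(lat1), n))
  p2 <- cbind(rep_len(as.numeric(lon2), n), rep_len(as.numeric(lat2), n))
  geosphere::distGeo(p1, p2) / 1000
}

#' Compare cline predictors by AIC
#'
#' Fits one joint two-continent logistic cline per candidate predictor
#' (substituting the predictor for the spatial axis) and ranks the fits by
#' AIC. Predictors with fewer than 2 distinct values are skipped with a
#' warning.
#'
#' @param individuals data.frame of individuals with an `A` column.
#' @param predictors named list (or data.frame) of per-individual predictor
#'   vectors.
#' @param M fixed asymptotic maximum or `"free"`.
#' @param n_starts,seed multi-start controls per fit.
#' @return object of class `predictor_comparison`: data.frame with one row
#'   per predictor (`predictor`, `rss`, `aic`, `delta_aic`), sorted by AIC,
#'   with the fits in `attr(, "fits")`.
#' @export
compare_cline_predictors <- function(individuals, predictors, M = 0.84,
                                     n_starts = 100, seed = 1) {
  stopifnot("A" %in% names(individuals))
  A <- individuals$A
  fits <- list()
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    ok <- is.finite(x) & is.finite(A)
    if (length(unique(x[ok])) < 2) {
      warning("skipping predictor with < 2 distinct values: ", nm)
      next
    }
    fits[[nm]] <- fit_logistic_cline(x[ok], A[ok], M = M,
                                     n_starts = n_starts, seed = seed,
                                     predictor = nm)
  }
  if (!length(fits)) stop("no usable predictors")
  out <- data.frame(predictor = names(fits),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  attr(out, "fits") <- fits
  class(out) <- c("predictor_comparison", "data.frame")
  out
}

#' Fit per-SNP logistic clines to population ancestry frequencies
#'
#' Fits the logistic cline with `M = 1` to each SNP's population mean
#' A-ancestry frequencies across latitude, as for a hybrid-zone continent
#' whose sampling spans the full cline. SNPs whose frequencies are all
#' equal are flagged unfit. The center is bounded to the sampled latitude
#' range widened by one range-width on each side.
#'
#' @param freqs loci x populations frequency matrix.
#' @param latitudes per-population predictor values aligned to columns.
#' @param M asymptotic maximum (default 1 for per-SNP fits).
#' @param n_starts random starts per SNP (small by design; a deterministic
#'   start at the previous SNP's optimum is added).
#' @param seed RNG seed.
#' @return data.frame: `snp`, `b`, `c`, `width`, `rss`, `converged`.
#' @export
fit_snp_clines <- function(freqs, latitudes, M = 1, n_starts = 4, seed = 1) {
  freqs <- as.matrix(freqs)
  stopifnot(ncol(freqs) == length(latitudes))
  L <- nrow(freqs)
  rng <- range(latitudes)
  c_bounds <- rng + c(-1, 1) * diff(rng)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  starts <- cbind(stats::runif(n_starts, -5, 5),
                  stats::runif(n_starts, rng[1], rng[2]))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  b <- cc <- rss <- rep(NA_real_, L)
  conv <- rep(FALSE, L)
  prev <- NULL
  for (l in seq_len(L)) {
    A <- freqs[l, ]
    if (max(A) - min(A) == 0) next     # unfittable: flat frequencies
    best <- NULL
    ss <- rbind(starts, prev)
    for (s in seq_len(nrow(ss))) {
      fit <- tryCatch(
        stats::optim(ss[s, ], cline_rss, x = latitudes, A = A, M_fixed = M,
                     method = "L-BFGS-B", lower = c(-50, c_bounds[1]),
                     upper = c(50, c_bounds[2]),
                     control = list(factr = 1e4, maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) next
    b[l] <- best$par[1]; cc[l] <- best$par[2]; rss[l] <- best$value
    conv[l] <- TRUE
    prev <- best$par
  }
  data.frame(snp = seq_len(L), b = b, c = cc,
             width = ifelse(b != 0, 4 / abs(b), Inf),
             rss = rss, converged = conv)
}

#' Compose a phenotype cline from an ancestry cline and a linear model
#'
#' Returns the function `latitude -> intercept + slope * A_hat(latitude)`
#' where `A_hat` is the fitted genome-wide ancestry cline: the expected
#' phenotype cline when the phenotype is fully determined by genome-wide
#' ancestry.
#'
#' @param cline a fitted `cline_fit`.
#' @param intercept,slope linear-model coefficients (phenotype units and
#'   phenotype units per unit ancestry).
#' @return function of latitude.
#' @export
predict_phenotype_cline <- function(cline, intercept, slope) {
  stopifnot(inherits(cline, "cline_fit"))
  force(intercept); force(slope)
  function(latitude) intercept + slope * predict(cline, latitude)
}
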