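#' End-to-end pipeline run from a single configuration
#'
#' Orchestrates the stages synth -> genome-wide clines -> drift-null
#' outlier scan -> steep-cline enrichment -> diversity -> admixture
#' mapping on a synthetic dataset, writing TSV/BED artifacts and a
#' manifest with checksums. Identical configuration and seed give
#' identical checksums.
#'
#' @param config a [synth_config()] (or a list with elements `synth` = a
#'   config and `stages` = character subset of
#'   `c("cline", "scan", "steep", "diversity", "map")`).
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived as small fixed
#'   offsets.
#' @param n_null loci for the drift-null ensembles (default 10000 at
#'   pipeline scale).
#' @param n_boot bootstrap replicates for enrichment (default 1000 at
#'   pipeline scale).
#' @return data.frame manifest (`file`, `md5`), invisibly the full paths.
#' @export
run_pipeline <- function(config = synth_config(), out_dir, seed = 1,
                         n_null = 10000, n_boot = 1000) {
  stages <- c("cline", "scan", "steep", "diversity", "map")
  if (!inherits(config, "synth_config")) {
    stopifnot(is.list(config), inherits(config$synth, "synth_config"))
    if (!is.null(config$stages)) stages <- config$stages
    config <- config$synth
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", name, sprintf(...)))
  }

  log_stage("synth", "simulating dataset (seed %d, %d loci)", seed,
            config$n_loci)
  ds <- simulate_hybrid_zones(config, seed = seed)
  paths <- c(paths, write_synthetic_dataset(ds, out_dir))

  ind <- ds$individuals
  fits <- list()
  if ("cline" %in% stages) {
    for (ct in c("N", "S")) {
      d <- ind[ind$continent == ct, ]
      fits[[ct]] <- fit_logistic_cline(abs(d$latitude), d$A, M = config$M,
                                       n_starts = 50, seed = seed + 10,
                                       predictor = "abs_latitude")
      log_stage("cline", "%s: c = %.3f, b = %.3f, width = %.2f deg", ct,
                fits[[ct]]$c, fits[[ct]]$b, fits[[ct]]$width)
    }
    cl <- data.frame(continent = names(fits),
                     M = vapply(fits, `[[`, 0, "M"),
                     b = vapply(fits, `[[`, 0, "b"),
                     c = vapply(fits, `[[`, 0, "c"),
                     width = vapply(fits, `[[`, 0, "width"),
                     rss = vapply(fits, `[[`, 0, "rss"),
                     aic = vapply(fits, `[[`, 0, "aic"))
    p <- file.path(out_dir, "cline_fits.tsv")
    utils::write.table(cl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  if ("scan" %in% stages) {
    km <- compute_K(ds$freqs, ds$populations$alpha)
    ens <- simulate_null("mvn-full", k_model = km, n_loci = n_null,
                         seed = seed + 20)
    obs <- continental_means(ds$freqs, ds$populations$continent)
    nul <- continental_means(ens$freqs, ds$populations$continent)
    th <- lapply(names(obs), function(ct)
      list(high = fdr_thresholds(obs[[ct]], nul[[ct]], "high"),
           low = fdr_thresholds(obs[[ct]], nul[[ct]], "low")))
    names(th) <- names(obs)
    res <- classify_outliers(obs, th)
    p <- file.path(out_dir, "outliers.tsv")
    utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    shared <- ifelse(res$shared_high,
                     pmax(res$fdr_high_N, res$fdr_high_S), NA_integer_)
    regions <- merge_outlier_regions(ds$snps, shared,
                                     direction = "high-A",
                                     continents = "N,S")
    p <- file.path(out_dir, "shared_high_regions.bed")
    write_regions_bed(regions, p)
    paths <- c(paths, p)
    log_stage("scan", "%d shared high-A SNPs in %d regions",
              sum(res$shared_high, na.rm = TRUE), nrow(regions))
  }

  if ("steep" %in% stages) {
    s_pops <- ds$populations$continent == "S"
    km_s <- compute_K(ds$freqs[, s_pops, drop = FALSE],
                      ds$populations$alpha[s_pops])
    obs_fits <- fit_snp_clines(ds$freqs[, s_pops, drop = FALSE],
                               abs(ds$populations$latitude[s_pops]),
                               seed = seed + 30)
    enr <- enrichment_block_bootstrap(
      obs_fits$b, ds$snps, n_boot = n_boot, seed = seed + 31)
    p <- file.path(out_dir, "steep_enrichment.tsv")
    utils::write.table(enr$bins, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    log_stage("steep", "delta |b| lowest-highest bin: %.4f", enr$delta_b)
  }

  if ("diversity" %in% stages) {
    # predicted diversity per population from panels + admixture weights
    pred <- vapply(seq_len(nrow(ds$populations)), function(i) {
      pop <- ds$populations$population[i]
      bees <- ind[ind$population == pop, ]
      wgt <- c(A = mean(bees$A), C = mean(bees$C), M = mean(bees$M))
      predicted_pi_from_admixture(wgt / sum(wgt), ds$panel_freqs,
                                  ds$mappable_sites, population = pop)$pi
    }, 0)
    dv <- data.frame(population = ds$populations$population,
                     predicted_pi = pred)
    p <- file.path(out_dir, "diversity_predicted.tsv")
    utils::write.table(dv, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    log_stage("diversity", "predicted pi for %d populations", nrow(dv))
  }

  if ("map" %in% stages) {
    scan <- admixture_map_scan(ind, ds$dosages)
    thr <- admixture_threshold(47.6, ds$layout)
    p <- file.path(out_dir, "admixture_map.tsv")
    utils::write.table(scan, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    writeLines(sprintf("threshold\t%.6g", thr),
               file.path(out_dir, "admixture_threshold.tsv"))
    paths <- c(paths, file.path(out_dir, "admixture_threshold.tsv"))
    log_stage("map", "min p = %.3g, threshold = %.3g",
              min(scan$p, na.rm = TRUE), thr)
  }

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
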