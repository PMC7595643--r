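#' Genome layout: chromosome table plus a windowed recombination map
#'
#' A genome layout holds the ordered chromosomes (name, physical length in
#' bp) and a windowed recombination map giving a constant rate (cM/Mb)
#' within each window. Cumulative genetic positions (cM) are computed
#' internally from the per-window rates.
#'
#' @param chromosomes data.frame with columns `chrom` and `length` (bp).
#' @param map_windows data.frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open) and `rate` (cM/Mb, non-negative). Windows must
#'   be sorted and non-overlapping within each chromosome and every
#'   chromosome needs at least one window.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, map_windows) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(map_windows))
  need_c <- c("chrom", "length")
  need_w <- c("chrom", "start", "end", "rate")
  if (!all(need_c %in% names(chromosomes)))
    stop("chromosomes needs columns: ", paste(need_c, collapse = ", "))
  if (!all(need_w %in% names(map_windows)))
    stop("map_windows needs columns: ", paste(need_w, collapse = ", "))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  map_windows$chrom <- as.character(map_windows$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  if (any(map_windows$rate < 0)) stop("recombination rates must be >= 0")
  if (any(map_windows$end <= map_windows$start))
    stop("map windows must have end > start")
  missing_chr <- setdiff(chromosomes$chrom, map_windows$chrom)
  if (length(missing_chr))
    stop("chromosomes without map windows: ", paste(missing_chr, collapse = ", "))
  extra_chr <- setdiff(map_windows$chrom, chromosomes$chrom)
  if (length(extra_chr))
    stop("map windows on unknown chromosomes: ", paste(extra_chr, collapse = ", "))

  # per-chromosome: sort, check overlap, precompute cumulative cM at starts
  cum <- lapply(split(map_windows, map_windows$chrom), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    if (any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping map windows on chromosome ", w$chrom[1])
    span_cm <- (w$end - w$start) * w$rate / 1e6
    w$cm_start <- cumsum(c(0, span_cm[-length(span_cm)]))
    w$cm_end <- w$cm_start + span_cm
    w
  })
  structure(
    list(chromosomes = chromosomes, map = cum),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  nw <- sum(vapply(x$map, nrow, 0L))
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      nw, "map windows,",
      sprintf("%.1f Mb, %.1f cM total\n",
              sum(x$chromosomes$length) / 1e6, total_map_cm(x)))
  invisible(x)
}

#' Total genetic map length of a layout, in cM
#' @param layout a `genome_layout`.
#' @return numeric scalar (cM).
#' @export
total_map_cm <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(vapply(layout$map, function(w) w$cm_end[nrow(w)], 0))
}

#' Interpolate genetic map position (cM) for physical positions
#'
#' Piecewise-linear interpolation of cumulative genetic position from the
#' windowed recombination map. Positions beyond the mapped span on a
#' chromosome are extrapolated linearly using the rate of the nearest
#' mapped window, so the result is monotone non-decreasing in `pos`.
#'
#' @param layout a `genome_layout`.
#' @param chrom chromosome name (scalar).
#' @param pos vector of 1-based physical positions (bp), all > 0.
#' @return numeric vector of genetic positions (cM).
#' @export
interpolate_genetic_position <- function(layout, chrom, pos) {
  stopifnot(inherits(layout, "genome_layout"))
  chrom <- as.character(chrom)
  w <- layout$map[[chrom]]
  if (is.null(w)) stop("unknown chromosome: ", chrom)
  if (any(pos <= 0)) stop("positions must be > 0")
  n <- nrow(w)
  # map each pos to its containing / nearest window
  idx <- findInterval(pos, w$start)       # 0 if before first window
  cm <- numeric(length(pos))
  before <- idx == 0
  if (any(before))
    cm[before] <- (pos[before] - w$start[1]) * w$rate[1] / 1e6
  inside <- !before
  if (any(inside)) {
    i <- idx[inside]
    p <- pos[inside]
    # within window i when p <= end; past window i (inside a gap or past
    # the map) extend at window i's rate from its end
    base <- w$cm_start[i] + pmin(p - w$start[i], w$end[i] - w$start[i]) *
      w$rate[i] / 1e6
    over <- pmax(p - w$end[i], 0)
    # gap between window i and i+1: continue at rate of nearest window;
    # we use the left window's rate, then shift so cm is continuous at
    # the next window start (gaps get the left rate, capped to keep
    # monotonicity with the next window's cm_start)
    nxt <- pmin(i + 1L, n)
    has_next <- i < n
    gap_cm <- over * w$rate[i] / 1e6
    cap <- ifelse(has_next, pmax(w$cm_start[nxt] - w$cm_start[i] -
                                   (w$cm_end[i] - w$cm_start[i]), 0), Inf)
    cm[inside] <- base + pmin(gap_cm, cap)
  }
  cm
}

#' Recombination rate (cM/Mb) of the window containing each position
#'
#' Positions outside the mapped span take the nearest window's rate.
#'
#' @inheritParams interpolate_genetic_position
#' @return numeric vector of rates (cM/Mb).
#' @export
window_rate_at <- function(layout, chrom, pos) {
  stopifnot(inherits(layout, "genome_layout"))
  w <- layout$map[[as.character(chrom)]]
  if (is.null(w)) stop("unknown chromosome: ", chrom)
  idx <- pmax(findInterval(pos, w$start), 1L)
  w$rate[idx]
}

#' Build a SNP table with genetic positions and local recombination rates
#'
#' @param layout a `genome_layout`.
#' @param chrom,pos parallel vectors of chromosome names and 1-based bp.
#' @return data.frame with `chrom`, `pos`, `cm`, `recomb_rate`, sorted by
#'   chromosome (layout order) then position.
#' @export
snp_table <- function(layout, chrom, pos) {
  stopifnot(inherits(layout, "genome_layout"), length(chrom) == length(pos))
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), layout$chromosomes$chrom)
  if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
  len <- stats::setNames(layout$chromosomes$length, layout$chromosomes$chrom)
  if (any(pos < 1 | pos > len[chrom]))
    stop("SNP positions outside chromosome length")
  ord <- order(match(chrom, layout$chromosomes$chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  out <- data.frame(chrom = chrom, pos = pos, cm = NA_real_,
                    recomb_rate = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out$cm[sel] <- interpolate_genetic_position(layout, ch, pos[sel])
    out$recomb_rate[sel] <- window_rate_at(layout, ch, pos[sel])
  }
  out
}

# ---- readers -------------------------------------------------------------

read_tsv_checked <- function(path, required, what) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  message(sprintf("read %s: %d rows from %s", what, nrow(x), path))
  x
}

check_prop <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    stop("column '", name, "' has values outside [0,1]: e.g. ",
         x[which(bad)[1]])
  x
}

check_lat <- function(x) {
  bad <- !is.na(x) & (x < -90 | x > 90)
  if (any(bad)) stop("latitude outside [-90,90]: e.g. ", x[which(bad)[1]])
  x
}

#' Read a population table (TSV)
#'
#' Required columns: `population`, `continent`, `latitude`, `longitude`,
#' `n`. Optional: `alpha` (genome-wide mean A-ancestry proportion).
#'
#' @param path TSV file with header; missing values empty or "NA".
#' @return validated data.frame.
#' @export
read_population_table <- function(path) {
  x <- read_tsv_checked(path, c("population", "continent", "latitude",
                                "longitude", "n"), "population table")
  check_lat(x$latitude)
  if ("alpha" %in% names(x)) check_prop(x$alpha, "alpha")
  x
}

#' Read an individual table (TSV)
#'
#' One row per sampled bee. Required columns: `id`, `population`,
#' `continent`, `latitude`, and ancestry proportions `A`, `C`, `M`.
#' Optional: `wing_mm` (missing allowed), `feral`, `dataset`.
#'
#' @inheritParams read_population_table
#' @return validated data.frame; `wing_missing` column flags absent wings.
#' @export
read_individual_table <- function(path) {
  x <- read_tsv_checked(path, c("id", "population", "continent",
                                "latitude", "A", "C", "M"),
                        "individual table")
  check_lat(x$latitude)
  for (k in c("A", "C", "M")) check_prop(x[[k]], k)
  tot <- x$A + x$C + x$M
  if (any(!is.na(tot) & abs(tot - 1) > 1e-6))
    stop("ancestry proportions do not sum to 1 (tolerance 1e-6)")
  if (!"wing_mm" %in% names(x)) x$wing_mm <- NA_real_
  if (any(!is.na(x$wing_mm) & x$wing_mm <= 0))
    stop("wing_mm must be positive when present")
  x$wing_missing <- is.na(x$wing_mm)
  x
}

#' Read a loci x populations ancestry frequency matrix (TSV)
#'
#' First two columns `chrom`, `pos`; remaining columns one per population,
#' holding mean A-ancestry frequencies in [0,1].
#'
#' @inheritParams read_population_table
#' @return list with `snps` (data.frame chrom,pos) and `freqs` (matrix).
#' @export
read_ancestry_freqs <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "pos"), "ancestry frequency matrix")
  pops <- setdiff(names(x), c("chrom", "pos"))
  if (!length(pops)) stop("no population columns found")
  f <- as.matrix(x[, pops, drop = FALSE])
  storage.mode(f) <- "double"
  for (p in pops) check_prop(f[, p], p)
  list(snps = x[, c("chrom", "pos")], freqs = f)
}

#' Read a windowed recombination map plus chromosome lengths (TSV)
#'
#' @param map_path TSV with columns `chrom`, `start`, `end`, `rate`.
#' @param chrom_path TSV with columns `chrom`, `length`; if `NULL`,
#'   chromosome lengths default to each chromosome's last window end.
#' @return a `genome_layout`.
#' @export
read_genetic_map <- function(map_path, chrom_path = NULL) {
  w <- read_tsv_checked(map_path, c("chrom", "start", "end", "rate"),
                        "recombination map")
  if (is.null(chrom_path)) {
    chr <- stats::aggregate(end ~ chrom, data = w, FUN = max)
    names(chr) <- c("chrom", "length")
  } else {
    chr <- read_tsv_checked(chrom_path, c("chrom", "length"), "chromosomes")
  }
  genome_layout(chr, w)
}

# ---- regions and BED -----------------------------------------------------

#' Construct an outlier-region table
#'
#' Regions use BED conventions: 0-based half-open `[start, end)`.
#'
#' @param chrom,start,end vectors defining intervals (`start < end`).
#' @param direction per-region label, e.g. `"high-A"` or `"low-A"`.
#' @param min_fdr best (lowest) FDR class inside the region, in percent.
#' @param continents which hybrid zones support the region (e.g. "N,S").
#' @param n_snps number of significant SNPs inside.
#' @return data.frame of class `region_table`.
#' @export
region_table <- function(chrom, start, end, direction,
                         min_fdr = NA_integer_, continents = NA_character_,
                         n_snps = NA_integer_) {
  if (length(chrom) && any(start >= end)) stop("regions need start < end")
  if (!length(chrom)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      min_fdr = integer(), continents = character(),
                      n_snps = integer(), stringsAsFactors = FALSE)
    class(out) <- c("region_table", "data.frame")
    return(out)
  }
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end),
                    direction = as.character(direction),
                    min_fdr = as.integer(min_fdr),
                    continents = as.character(continents),
                    n_snps = as.integer(n_snps), stringsAsFactors = FALSE)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Write outlier regions as BED (0-based half-open)
#'
#' Columns: chrom, start, end, name (= direction), score (= min FDR in
#' percent), then `continents` and `n_snps` as extra columns. No header.
#'
#' @param regions a `region_table` (or compatible data.frame).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- c("chrom", "start", "end", "direction", "min_fdr",
            "continents", "n_snps")
  stopifnot(all(cols %in% names(regions)))
  utils::write.table(regions[, cols], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a regions BED written by [write_regions_bed()]
#' @param path BED path.
#' @return a `region_table`.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0)
    return(region_table(character(), integer(), integer(), character()))
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  names(x)[1:5] <- c("chrom", "start", "end", "direction", "min_fdr")
  if (ncol(x) >= 6) names(x)[6] <- "continents" else x$continents <- NA
  if (ncol(x) >= 7) names(x)[7] <- "n_snps" else x$n_snps <- NA
  region_table(x$chrom, x$start, x$end, x$direction, x$min_fdr,
               x$continents, x$n_snps)
}

#' Read a gene/QTL interval BED file (first 4+ columns used)
#' @param path BED path (chrom, start, end, name[, ...]); no header.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_genes_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    name = if (ncol(x) >= 4) as.character(x[[4]]) else
                      paste0("feature", seq_len(nrow(x))),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED intervals need start < end")
  out
}
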