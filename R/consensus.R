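#' Build consensus regions from peak groups
#'
#' One interval per group, summarizing the member peaks under one of four
#' rules. When peaks were identified only in a subset of replicates, the
#' consensus is determined from that subset.
#' \describe{
#'   \item{MAX}{the maximal span `[min start, max end)` over members.}
#'   \item{SMT}{between the summits: `[min summit, max summit + 1)`,
#'     widened symmetrically to `min_width` when narrower.}
#'   \item{ASF}{footprint-sized window centred on the average summit:
#'     `[s - floor(f/2), s + ceiling(f/2))` for footprint f.}
#'   \item{ASW}{like ASF but sized by the average peak width.}
#' }
#' SMT/ASF/ASW need summits; members without one fall back to the interval
#' midpoint (reported via the `summit_fallback` attribute). The average
#' summit is rounded half-up. Regions are clipped to chromosome bounds.
#'
#' @param groups a `peak_groups` object.
#' @param method one of "MAX", "SMT", "ASF", "ASW".
#' @param sizes chromosome sizes (named vector, see [chrom_sizes()]).
#' @param footprint bp, required for ASF (> 0).
#' @param avg_width bp for ASW; default is the mean width of all member peaks
#'   pooled across replicates (a dataset-level average is more stable than a
#'   per-group one).
#' @param min_width minimum SMT width in bp (default 50).
#' @return data frame of class `consensus_regions`: group_id, method, chrom,
#'   start, end, avg_summit.
#' @export
build_consensus <- function(groups, method = c("MAX", "SMT", "ASF", "ASW"),
                            sizes, footprint = NULL, avg_width = NULL,
                            min_width = 50) {
  stopifnot(inherits(groups, "peak_groups"))
  method <- match.arg(method)
  sizes <- chrom_sizes(sizes)
  pk <- groups$peaks
  unknown <- setdiff(unique(pk$chrom), names(sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (method == "ASF") {
    if (is.null(footprint) || footprint <= 0)
      stop("ASF requires footprint > 0")
    width <- footprint
  }
  if (method == "ASW") {
    if (is.null(avg_width)) avg_width <- mean(pk$end - pk$start)
    if (avg_width <= 0) stop("ASW requires avg_width > 0")
    width <- avg_width
  }
  n_fallback <- 0L
  if (method != "MAX") {
    miss <- is.na(pk$summit)
    n_fallback <- length(unique(pk$group_id[miss]))
    pk$summit[miss] <- floor((pk$start[miss] + pk$end[miss]) / 2)
  }
  gsp <- split(seq_len(nrow(pk)), pk$group_id)
  rows <- lapply(names(gsp), function(gid) {
    i <- gsp[[gid]]
    chrom <- pk$chrom[i][1]
    clen <- sizes[[chrom]]
    avg_smt <- if (method == "MAX") NA_real_ else
      floor(mean(pk$summit[i]) + 0.5)
    se <- switch(method,
      MAX = c(min(pk$start[i]), max(pk$end[i])),
      SMT = {
        lo <- min(pk$summit[i]); hi <- max(pk$summit[i]) + 1
        if (hi - lo < min_width) {
          pad <- min_width - (hi - lo)
          lo <- lo - floor(pad / 2); hi <- hi + ceiling(pad / 2)
        }
        c(lo, hi)
      },
      ASF = ,
      ASW = c(avg_smt - floor(width / 2), avg_smt + ceiling(width / 2))
    )
    start <- max(0, se[1]); end <- min(clen, se[2])
    if (start >= end)
      stop("consensus region for ", gid, " empties after clipping")
    data.frame(group_id = gid, method = method, chrom = chrom,
               start = start, end = end, avg_summit = avg_smt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summit_fallback") <- n_fallback
  class(out) <- unique(c("consensus_regions", class(out)))
  out
}

#' Reference regions from the deepest replicate
#'
#' The alternative to consensus building used by single-reference study
#' designs: take the peak intervals of the replicate with the most mapped
#' reads as the regions quantified in every replicate. Ties break to the
#' lexicographically first label.
#'
#' @param peak_sets named list of `chip_peaks`.
#' @param totals named numeric vector of total mapped reads per replicate.
#' @return `consensus_regions` data frame with method "REF"; attribute
#'   `reference` names the chosen replicate.
#' @export
reference_regions <- function(peak_sets, totals) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  labels <- names(peak_sets)
  totals <- totals[labels]
  if (any(is.na(totals))) stop("totals must cover every replicate label")
  best <- sort(labels[totals == max(totals)])[1]
  pk <- validate_peaks(peak_sets[[best]])
  out <- data.frame(group_id = sprintf("ref_%05d", seq_len(nrow(pk))),
                    method = "REF", chrom = pk$chrom, start = pk$start,
                    end = pk$end, avg_summit = pk$summit,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$group_id <- sprintf("ref_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "reference") <- best
  class(out) <- unique(c("consensus_regions", class(out)))
  out
}

#' RPKM quantification of regions across replicates
#'
#' For each region and replicate, count reads overlapping the region by at
#' least one nucleotide (a read counts once per region, but may count toward
#' several overlapping regions) and normalize:
#' RPKM = count * 1e9 / (region length in bp * total mapped reads).
#'
#' @param regions data frame with group_id/chrom/start/end (e.g. from
#'   [build_consensus()] or [make_promoters()]).
#' @param read_sets named list of `chip_reads`, one per replicate.
#' @param totals named numeric vector of total mapped reads per replicate;
#'   defaults to `nrow` of each read set.
#' @return object of class `coverage_matrix`: list with `regions`,
#'   `rpkm` (regions x replicates matrix), `counts` (same shape),
#'   `totals`.
#' @export
quantify <- function(regions, read_sets, totals = NULL) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  if (is.null(totals))
    totals <- vapply(read_sets, nrow, numeric(1))
  totals <- totals[names(read_sets)]
  if (any(is.na(totals) | totals <= 0)) stop("totals must be positive")
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region")
  gr <- as_gr(regions)
  counts <- vapply(names(read_sets), function(l) {
    GenomicRanges::countOverlaps(gr, as_gr(validate_reads(read_sets[[l]])))
  }, numeric(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(regions$group_id, names(read_sets)))
  rpkm <- counts * 1e9 / outer(len, totals)
  structure(list(regions = regions, rpkm = rpkm, counts = counts,
                 totals = totals),
            class = "coverage_matrix")
}

#' Detection-above-background Z-test
#'
#' Tests whether a region's RPKM in one replicate exceeds that replicate's
#' background, defined as the RPKM values of its own called peaks below
#' their 25th percentile. z = (target - mean(bg)) / sd(bg) with the sample
#' (n-1) standard deviation; one-sided upper-tail normal p; detected when
#' p < alpha.
#'
#' @param target_rpkm value to test.
#' @param background_rpkms numeric vector, >= 3 values with nonzero spread.
#' @param alpha significance level (default 0.05).
#' @return list: z, p, detected.
#' @export
dabg <- function(target_rpkm, background_rpkms, alpha = 0.05) {
  bg <- background_rpkms[is.finite(background_rpkms)]
  if (length(bg) < 3) stop("background needs >= 3 values")
  s <- stats::sd(bg)
  if (s == 0) stop("background has zero spread; widen the background set")
  z <- (target_rpkm - mean(bg)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, detected = p < alpha)
}

# background values: strictly below the 25th percentile (linear interpolation)
dabg_background <- function(rpkms) {
  q <- stats::quantile(rpkms, 0.25, names = FALSE, type = 7)
  rpkms[rpkms < q]
}

#' Screen dropout replicates for detection above background
#'
#' For every (group, replicate) pair where the replicate did NOT call a peak
#' in the group, asks whether that replicate's coverage in the consensus
#' region is nevertheless above its own background — evidence the caller
#' missed a genuine site. Each replicate's background is the low quartile of
#' the RPKM distribution over its own called peaks, so replicates are judged
#' against their own depth and noise floor.
#'
#' @param groups a classified `peak_groups` object (see [classify_groups()]).
#' @param coverage `coverage_matrix` over the groups' consensus regions
#'   (row names are group ids).
#' @param peak_rpkms named list: per replicate, the RPKM values of its own
#'   called peaks (quantified in that replicate). Replicates with fewer than
#'   `min_peaks` peaks are skipped with a warning.
#' @param alpha significance level.
#' @param method "ztest" (default) or "threshold" (literal rule: detected
#'   when the target RPKM exceeds the replicate's 25th percentile).
#' @param min_peaks minimum called peaks for a usable background (default 12).
#' @return data frame of class `dabg_results`: group_id, replicate_id, class,
#'   rpkm, z, p, detected; attribute `confirmation_rates` holds the per-class
#'   fraction of tested cells detected.
#' @export
dabg_screen <- function(groups, coverage, peak_rpkms, alpha = 0.05,
                        method = c("ztest", "threshold"), min_peaks = 12L) {
  stopifnot(inherits(groups, "peak_groups"),
            inherits(coverage, "coverage_matrix"))
  method <- match.arg(method)
  if (is.null(groups$groups$class))
    groups <- classify_groups(groups)
  gdf <- groups$groups
  reps <- colnames(coverage$rpkm)
  usable <- reps
  bg <- list(); thr <- list()
  for (r in reps) {
    v <- peak_rpkms[[r]]
    if (is.null(v) || length(v) < min_peaks) {
      warning("replicate ", r, " has < ", min_peaks,
              " called peaks; background too small, skipping")
      usable <- setdiff(usable, r)
      next
    }
    b <- dabg_background(v)
    # e.g. many zero-RPKM calls in a shallow library: nothing strictly below
    # the quartile, or no spread to test against
    if (length(b) < 3 || stats::sd(b) == 0) {
      warning("replicate ", r,
              " has a degenerate low-quartile background; skipping")
      usable <- setdiff(usable, r)
      next
    }
    bg[[r]] <- b
    thr[[r]] <- stats::quantile(v, 0.25, names = FALSE)
  }
  sup <- strsplit(gdf$support, ",", fixed = TRUE)
  out <- list()
  for (i in seq_len(nrow(gdf))) {
    gid <- gdf$group_id[i]
    if (!gid %in% rownames(coverage$rpkm)) next
    for (r in setdiff(usable, sup[[i]])) {
      tgt <- coverage$rpkm[gid, r]
      if (method == "ztest") {
        res <- dabg(tgt, bg[[r]], alpha)
      } else {
        res <- list(z = NA_real_, p = NA_real_, detected = tgt > thr[[r]])
      }
      out[[length(out) + 1]] <- data.frame(
        group_id = gid, replicate_id = r, class = gdf$class[i],
        rpkm = tgt, z = res$z, p = res$p, detected = res$detected,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group_id = character(), replicate_id = character(),
               class = character(), rpkm = numeric(), z = numeric(),
               p = numeric(), detected = logical())
  rates <- if (nrow(res)) tapply(res$detected, res$class, mean) else numeric()
  attr(res, "confirmation_rates") <- rates
  class(res) <- unique(c("dabg_results", class(res)))
  res
}
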