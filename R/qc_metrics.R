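#' PCR bottleneck coefficient
#'
#' Library-complexity proxy: the fraction of uniquely mapped reads that are
#' non-redundant. Distinctness is keyed on the read 5' end
#' (chrom, position, strand), ENCODE-style; the 5' end is `start` for
#' plus-strand reads and `end - 1` for minus-strand reads. Uniqueness of
#' mapping is the caller's responsibility.
#'
#' @param rds a `chip_reads` data frame (nonempty).
#' @return list with `pbc` (distinct/total), `total_reads`,
#'   `distinct_positions`, and `flag_ok` (TRUE when pbc > 0.7, the level above
#'   which libraries are regarded as complex).
#' @export
pbc <- function(rds) {
  rds <- validate_reads(rds)
  n <- nrow(rds)
  if (n == 0) stop("pbc() needs a nonempty read set")
  p5 <- ifelse(rds$strand == "+", rds$start, rds$end - 1)
  key <- paste(rds$chrom, p5, rds$strand)
  d <- length(unique(key))
  list(pbc = d / n, total_reads = n, distinct_positions = d,
       flag_ok = (d / n) > 0.7)
}

#' Fraction of reads in peaks
#'
#' Global-enrichment proxy: the fraction of reads overlapping any called peak
#' by at least one nucleotide. A read inside several peaks counts once.
#'
#' @param rds a `chip_reads` data frame (nonempty).
#' @param pks a `chip_peaks` data frame; empty peak set gives 0 (no
#'   enrichment captured), which is valid.
#' @return ratio in \[0, 1\].
#' @export
frip <- function(rds, pks) {
  rds <- validate_reads(rds)
  if (nrow(rds) == 0) stop("frip() needs a nonempty read set")
  pks <- validate_peaks(pks)
  if (nrow(pks) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(as_gr(rds), as_gr(pks))
  sum(hits > 0) / nrow(rds)
}

#' Strand cross-correlation profile
#'
#' For each strand shift s, the Pearson correlation between the per-position
#' 5'-end count vector of plus-strand reads and that of minus-strand reads
#' shifted left by s. The vectors run over the whole occupied span padded
#' with zeros (correlating only co-occupied positions would discard the
#' shared zeros that carry the co-occupancy signal and drive every
#' correlation negative). In an enriched library the profile peaks near the
#' fragment length; a "phantom" peak at the read length is excluded by a
#' guard window when locating the fragment peak.
#'
#' @param rds a `chip_reads` data frame with both strands present.
#' @param shift_range inclusive bp bounds of the shift scan, default c(0, 300).
#' @param read_length read length in bp (phantom-peak position).
#' @param shift_step scan step in bp (default 1).
#' @param guard half-width in bp of the phantom-peak exclusion window around
#'   `read_length` (default 10).
#' @return object of class `cc_profile`: list with `shifts`, `cc`,
#'   `fragment_peak_shift`, `read_length`.
#' @export
strand_cross_correlation <- function(rds, shift_range = c(0, 300),
                                     read_length, shift_step = 1L,
                                     guard = 10L) {
  rds <- validate_reads(rds)
  if (!all(c("+", "-") %in% rds$strand))
    stop("cross-correlation needs reads on both strands")
  stopifnot(length(shift_range) == 2, shift_range[1] <= shift_range[2])
  # collapse chromosomes into one axis with spacing so shifts never wrap
  chroms <- sort(unique(rds$chrom))
  span <- max(rds$end) + abs(shift_range[2]) + abs(shift_range[1]) + 1
  off <- stats::setNames((seq_along(chroms) - 1) * span, chroms)
  p5 <- ifelse(rds$strand == "+", rds$start, rds$end - 1) + off[rds$chrom]
  cnt <- function(v) {
    u <- sort(unique(v))
    list(pos = u, n = as.numeric(tabulate(match(v, u), nbins = length(u))))
  }
  plus <- cnt(p5[rds$strand == "+"])
  minus <- cnt(p5[rds$strand == "-"])
  shifts <- seq(shift_range[1], shift_range[2], by = shift_step)
  # Pearson over the padded axis via sufficient statistics: only the sparse
  # cross term sum(plus[p] * minus[p + s]) varies with the shift. A margin of
  # the scanned extremes keeps every shifted minus position on the axis, so
  # the axis length and both marginal sums are shift-independent.
  margin <- max(abs(shift_range))
  n_axis <- (max(plus$pos[length(plus$pos)], minus$pos[length(minus$pos)]) -
               min(plus$pos[1], minus$pos[1])) + 2 * margin + 1
  sx <- sum(plus$n); sxx <- sum(plus$n^2)
  sy <- sum(minus$n); syy <- sum(minus$n^2)
  vx <- n_axis * sxx - sx^2
  vy <- n_axis * syy - sy^2
  cc <- vapply(shifts, function(s) {
    i <- match(minus$pos - s, plus$pos)
    ok <- !is.na(i)
    sxy <- sum(plus$n[i[ok]] * minus$n[ok])
    den <- sqrt(vx * vy)
    if (den <= 0) return(0)
    (n_axis * sxy - sx * sy) / den
  }, numeric(1))
  eligible <- abs(shifts - read_length) > guard
  if (!any(eligible)) stop("guard window excludes every shift")
  peak_shift <- shifts[eligible][which.max(cc[eligible])]
  structure(list(shifts = shifts, cc = cc,
                 fragment_peak_shift = peak_shift,
                 read_length = read_length),
            class = "cc_profile")
}

#' NSC and RSC from a cross-correlation profile
#'
#' NSC is the fragment-length cross-correlation peak over the background
#' (the minimum correlation across the scanned shifts); RSC is the excess of
#' the fragment-length peak over background relative to the excess of the
#' read-length (phantom) peak over background.
#'
#' @param profile a `cc_profile` from [strand_cross_correlation()].
#' @return list with `nsc` and `rsc` (`rsc` is NA with a warning when the
#'   read-length correlation equals the background, which would divide by 0).
#' @export
nsc_rsc <- function(profile) {
  stopifnot(inherits(profile, "cc_profile"))
  ccmin <- min(profile$cc)
  cc_frag <- profile$cc[match(profile$fragment_peak_shift, profile$shifts)]
  i_rl <- which.min(abs(profile$shifts - profile$read_length))
  cc_rl <- profile$cc[i_rl]
  nsc <- cc_frag / ccmin
  if (cc_rl == ccmin) {
    warning("cc(read_length) equals background; RSC undefined")
    rsc <- NA_real_
  } else {
    rsc <- (cc_frag - ccmin) / (cc_rl - ccmin)
  }
  list(nsc = nsc, rsc = rsc)
}

#' Per-replicate QC report (QC1/QC2 metrics)
#'
#' Bundles PBC, FRIP and (optionally) NSC/RSC for one replicate.
#'
#' @param rds reads of one replicate.
#' @param pks peaks of that replicate, or NULL to skip FRIP.
#' @param replicate_id label.
#' @param read_length read length for cross-correlation; NULL skips NSC/RSC.
#' @param shift_range shift scan bounds.
#' @return one-row data frame: replicate_id, total_reads, distinct_positions,
#'   pbc, pbc_ok, n_peaks, frip, nsc, rsc.
#' @export
qc_report <- function(rds, pks = NULL, replicate_id = "rep",
                      read_length = NULL, shift_range = c(0, 300)) {
  b <- pbc(rds)
  fr <- if (!is.null(pks)) frip(rds, pks) else NA_real_
  nsc <- rsc <- NA_real_
  if (!is.null(read_length)) {
    prof <- strand_cross_correlation(rds, shift_range, read_length)
    nr <- nsc_rsc(prof)
    nsc <- nr$nsc; rsc <- nr$rsc
  }
  data.frame(replicate_id = replicate_id, total_reads = b$total_reads,
             distinct_positions = b$distinct_positions, pbc = b$pbc,
             pbc_ok = b$flag_ok,
             n_peaks = if (!is.null(pks)) nrow(pks) else NA_integer_,
             frip = fr, nsc = nsc, rsc = rsc,
             stringsAsFactors = FALSE)
}
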