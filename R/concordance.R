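#' Rank-bin a coverage column into equal-count ordinal groups
#'
#' Values are ranked ascending and cut into `n_bins` equal-count rank
#' quantiles. Ties are kept together: a tie run straddling a bin boundary
#' goes entirely to the lower bin (implemented by binning on the minimum
#' rank of each tie run). Any order-preserving transform of the values
#' leaves the bins unchanged.
#'
#' @param values numeric vector, length >= n_bins, not all identical.
#' @param n_bins number of ordinal groups (default 5).
#' @return integer vector of bin labels in 1..n_bins.
#' @export
bin_coverage <- function(values, n_bins = 5L) {
  n <- length(values)
  if (n < n_bins) stop("need at least n_bins values")
  if (length(unique(values)) == 1)
    stop("all values identical; binning undefined")
  r <- rank(values, ties.method = "min")
  bins <- ceiling(r * n_bins / n)
  pmin(pmax(bins, 1L), as.integer(n_bins))
}

#' Weighted Kappa for ordinal agreement
#'
#' Chance-corrected agreement between two ordinal ratings of the same items:
#' kappa = 1 - sum(w * O) / sum(w * E), with disagreement weights
#' w_ij = |i-j|/(k-1) (linear, default) or its square (quadratic), O the
#' observed and E the chance-expected (outer product of marginals)
#' proportion tables. Values above 0.75 are conventionally read as
#' excellent agreement.
#'
#' @param bins_a,bins_b integer bin labels of equal length.
#' @param weights "linear" or "quadratic".
#' @param n_bins number of categories; default is the max observed label.
#' @return list: kappa, excellent (kappa > 0.75).
#' @export
weighted_kappa <- function(bins_a, bins_b, weights = c("linear", "quadratic"),
                           n_bins = NULL) {
  weights <- match.arg(weights)
  if (length(bins_a) != length(bins_b)) stop("length mismatch")
  k <- if (is.null(n_bins)) max(bins_a, bins_b) else n_bins
  o <- table(factor(bins_a, levels = 1:k),
             factor(bins_b, levels = 1:k)) / length(bins_a)
  pa <- rowSums(o); pb <- colSums(o)
  e <- outer(pa, pb)
  d <- abs(outer(1:k, 1:k, "-")) / (k - 1)
  w <- if (weights == "quadratic") d^2 else d
  kap <- 1 - sum(w * o) / sum(w * e)
  list(kappa = kap, excellent = kap > 0.75)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.
#'
#' @param values_a,values_b numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
spearman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("length mismatch")
  if (length(values_a) < 3) stop("need >= 3 pairs")
  if (stats::sd(rank(values_a)) == 0 || stats::sd(rank(values_b)) == 0)
    stop("zero variance in ranks")
  stats::cor(values_a, values_b, method = "spearman")
}

#' Bland-Altman agreement summary
#'
#' Per item: mean = (a+b)/2 and difference = a-b. Bias is the mean
#' difference; the limits of agreement are bias +/- 1.96 sample standard
#' deviations of the differences. The point table supports the conventional
#' difference-vs-mean plot.
#'
#' @param values_a,values_b numeric vectors of equal length >= 2 (two pairs
#'   suffice for a sample sd, though limits are then very unstable).
#' @param log2 compare on log2(x + 1) scale instead of raw values.
#' @return list: bias, loa_low, loa_high, points (data frame mean/diff).
#' @export
bland_altman <- function(values_a, values_b, log2 = FALSE) {
  if (length(values_a) != length(values_b)) stop("length mismatch")
  if (length(values_a) < 2) stop("need >= 2 pairs")
  if (log2) {
    values_a <- base::log2(values_a + 1)
    values_b <- base::log2(values_b + 1)
  }
  m <- (values_a + values_b) / 2
  d <- values_a - values_b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       points = data.frame(mean = m, diff = d))
}

#' Pairwise concordance report over a coverage matrix
#'
#' For every unordered pair of replicates: weighted Kappa of rank-binned
#' coverage (each column binned on its own distribution), Spearman
#' correlation, and Bland-Altman bias and limits of agreement.
#'
#' @param coverage a `coverage_matrix` (or a bare regions x replicates
#'   matrix of RPKM values).
#' @param n_bins ordinal groups for Kappa (default 5).
#' @param weights Kappa weights, "linear" or "quadratic".
#' @param log2 Bland-Altman on log2(x+1) scale.
#' @return data frame, one row per pair: rep_a, rep_b, kappa_weighted,
#'   kappa_excellent, spearman_rho, ba_bias, ba_loa_low, ba_loa_high,
#'   n_regions.
#' @export
concordance_report <- function(coverage, n_bins = 5L,
                               weights = c("linear", "quadratic"),
                               log2 = FALSE) {
  weights <- match.arg(weights)
  m <- if (inherits(coverage, "coverage_matrix")) coverage$rpkm else coverage
  stopifnot(is.matrix(m), ncol(m) >= 2)
  labels <- colnames(m)
  bins <- apply(m, 2, bin_coverage, n_bins = n_bins)
  out <- list()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in seq((i + 1), ncol(m))) {
      wk <- weighted_kappa(bins[, i], bins[, j], weights, n_bins = n_bins)
      rho <- spearman(m[, i], m[, j])
      ba <- bland_altman(m[, i], m[, j], log2 = log2)
      out[[length(out) + 1]] <- data.frame(
        rep_a = labels[i], rep_b = labels[j],
        kappa_weighted = wk$kappa, kappa_excellent = wk$excellent,
        spearman_rho = rho, ba_bias = ba$bias,
        ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
        n_regions = nrow(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
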