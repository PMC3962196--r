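# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# O(n^2) all-pairs overlap + union-find single-linkage grouping.
# df: data frame with chrom/start/end (0-based half-open).
# Returns a list of sorted member-index vectors (canonical partition).
oracle_group <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- lapply(unname(split(seq_len(n), roots)), sort)
  comps[order(vapply(comps, min, integer(1)))]
}

# canonical partition from a group_peaks() result, as member-index sets over
# the pooled (sorted) peak table
partition_of <- function(groups) {
  comps <- split(seq_len(nrow(groups$peaks)), groups$peaks$group_id)
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, min, integer(1)))]
}

# textbook weighted kappa via explicit loops:
# kappa_w = (Po_w - Pe_w) / (1 - Pe_w), agreement weights 1 - d_ij
oracle_kappa <- function(a, b, k, quadratic = FALSE) {
  n <- length(a)
  O <- matrix(0, k, k); for (t in seq_len(n)) O[a[t], b[t]] <- O[a[t], b[t]] + 1/n
  pa <- rowSums(O); pb <- colSums(O)
  po <- pe <- 0
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j) / (k - 1)
    if (quadratic) d <- d^2
    w <- 1 - d
    po <- po + w * O[i, j]
    pe <- pe + w * pa[i] * pb[j]
  }
  (po - pe) / (1 - pe)
}

# textbook Spearman: Pearson on average ranks, written out with explicit sums
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# McNemar chi-square(1) upper tail via the normal: P(X2 > s) = 2 P(Z < -sqrt(s))
oracle_mcnemar <- function(b, c) {
  if (b + c == 0) return(list(stat = 0, p = 1))
  s <- (b - c)^2 / (b + c)
  list(stat = s, p = 2 * stats::pnorm(-sqrt(s)))
}

# GRanges from a 0-based half-open table (test-side copy of the conversion)
as_gr_test <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

# quick literal constructors for fixtures
pk <- function(chrom, start, end, summit = NA_real_, rep_id = "r") {
  peaks(chrom, start, end, summit, NA_real_, rep_id)
}
rd <- function(chrom, start, end, strand = "+") {
  reads(chrom, start, end, strand)
}
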