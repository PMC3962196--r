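#' Cluster peaks across replicates into overlap groups
#'
#' Peaks from all replicates are pooled and clustered by single linkage:
#' two peaks are linked when they share at least one nucleotide, and a group
#' is a connected component of that overlap graph. With half-open intervals,
#' abutting peaks (`[100,200)` and `[200,300)`) share no base and stay apart.
#' Several consecutive peaks from one caller that all touch one broad peak
#' from another collapse into a single group; group counts are counts of
#' regions, not of member peaks.
#'
#' @param peak_sets named list, one `chip_peaks` data frame per replicate.
#'   Names are the replicate labels and must be unique.
#' @return object of class `peak_groups`: list with
#'   \describe{
#'     \item{peaks}{all member peaks with a `group_id` column}
#'     \item{groups}{one row per group: group_id, chrom, start, end (the
#'       span), support (comma-joined replicate labels), n_support}
#'     \item{n_replicates}{number of replicates in the experiment}
#'   }
#' @export
group_peaks <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 2)
  labels <- names(peak_sets)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("peak_sets must be a named list (replicate labels)")
  if (anyDuplicated(labels)) stop("duplicate replicate labels")
  all_pk <- do.call(rbind, lapply(labels, function(l) {
    p <- validate_peaks(peak_sets[[l]])
    if (nrow(p)) p$replicate_id <- l
    p
  }))
  all_pk <- sort_coords(all_pk)
  rownames(all_pk) <- NULL
  gr <- as_gr(all_pk)
  # min.gapwidth = 0: merge only true overlaps, never abutting ranges
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  comp <- GenomicRanges::sort(comp)
  hit <- GenomicRanges::findOverlaps(gr, comp)
  stopifnot(length(hit) == nrow(all_pk))   # every peak in exactly one component
  idx <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  all_pk$group_id <- sprintf("grp_%05d", idx)
  sup <- tapply(all_pk$replicate_id, all_pk$group_id,
                function(r) sort(unique(r)), simplify = FALSE)
  gdf <- data.frame(
    group_id = sprintf("grp_%05d", seq_along(comp)),
    chrom = as.character(GenomicRanges::seqnames(comp)),
    start = GenomicRanges::start(comp) - 1,
    end = as.numeric(GenomicRanges::end(comp)),
    stringsAsFactors = FALSE
  )
  gdf$support <- vapply(sup[gdf$group_id], paste, character(1), collapse = ",")
  gdf$n_support <- vapply(sup[gdf$group_id], length, integer(1))
  structure(list(peaks = all_pk, groups = gdf, n_replicates = length(labels)),
            class = "peak_groups")
}

#' Classify peak groups by replicate support
#'
#' Classes: `unique` (one replicate), `common_all` (every replicate),
#' `majority` (strictly more than half, but not all), `partial` (more than
#' one, at most half). Majority is strict: 3 of 5 and 2 of 3 qualify; 2 of 4
#' does not. `is_majority` marks the nested majority rule
#' (common_all groups are majority groups too).
#'
#' @param groups a `peak_groups` object.
#' @return the object with `class` and `is_majority` columns added to
#'   `$groups` and a `$class_counts` table (named counts per class).
#' @export
classify_groups <- function(groups) {
  stopifnot(inherits(groups, "peak_groups"))
  n <- groups$n_replicates
  s <- groups$groups$n_support
  if (any(s < 1 | s > n))
    stop("group support outside [1, n_replicates]: internal inconsistency")
  cls <- ifelse(s == 1, "unique",
         ifelse(s == n, "common_all",
         ifelse(s > n / 2, "majority", "partial")))
  groups$groups$class <- cls
  groups$groups$is_majority <- s > n / 2
  groups$class_counts <- c(
    unique = sum(cls == "unique"),
    partial = sum(cls == "partial"),
    majority = sum(cls == "majority"),
    common_all = sum(cls == "common_all"),
    majority_rule = sum(s > n / 2)   # majority + common_all
  )
  groups
}

#' Pairwise identification agreement between two replicates
#'
#' The simple agreement coefficient is the number of overlapping peaks over
#' all peaks identified in the pair (each peak counted once however many
#' partners it touches). McNemar's test examines the symmetry of the unique
#' peaks: with b = peaks unique to A and c = peaks unique to B, the statistic
#' is (b - c)^2 / (b + c) on 1 df (continuity correction optional); a
#' significant value means one replicate contributes disproportionately many
#' unique peaks.
#'
#' @param peaks_a,peaks_b `chip_peaks` data frames (both nonempty).
#' @param continuity apply Yates continuity correction (default FALSE).
#' @return one-row data frame: n_a, n_b, n_overlap_a, n_overlap_b,
#'   simple_agreement, mcnemar_statistic, mcnemar_p.
#' @export
pair_agreement <- function(peaks_a, peaks_b, continuity = FALSE) {
  peaks_a <- validate_peaks(peaks_a); peaks_b <- validate_peaks(peaks_b)
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0)
    stop("pair_agreement() needs nonempty peak sets on both sides")
  ga <- as_gr(peaks_a); gb <- as_gr(peaks_b)
  ov_a <- sum(GenomicRanges::countOverlaps(ga, gb) > 0)
  ov_b <- sum(GenomicRanges::countOverlaps(gb, ga) > 0)
  n_a <- nrow(peaks_a); n_b <- nrow(peaks_b)
  sa <- (ov_a + ov_b) / (n_a + n_b)
  b <- n_a - ov_a; cc <- n_b - ov_b
  if (b + cc == 0) {
    stat <- 0; p <- 1
  } else {
    num <- if (continuity) max(abs(b - cc) - 1, 0)^2 else (b - cc)^2
    stat <- num / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  data.frame(n_a = n_a, n_b = n_b, n_overlap_a = ov_a, n_overlap_b = ov_b,
             simple_agreement = sa, mcnemar_statistic = stat, mcnemar_p = p)
}

#' All pairwise agreements for an experiment
#'
#' @param peak_sets named list of `chip_peaks` (>= 2 replicates).
#' @param continuity passed to [pair_agreement()].
#' @return data frame with one row per unordered replicate pair.
#' @export
pairwise_agreement <- function(peak_sets, continuity = FALSE) {
  labels <- names(peak_sets)
  stopifnot(length(labels) >= 2)
  out <- list()
  for (i in seq_len(length(labels) - 1)) {
    for (j in seq((i + 1), length(labels))) {
      row <- pair_agreement(peak_sets[[i]], peak_sets[[j]], continuity)
      out[[length(out) + 1]] <- cbind(
        data.frame(rep_a = labels[i], rep_b = labels[j],
                   stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, out)
}
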