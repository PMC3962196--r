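#' Construct a peak table
#'
#' Peaks are stored as a plain data frame in 0-based half-open coordinates,
#' one row per called peak. `summit` is an absolute 0-based position (NA when
#' the caller supplied none) and must satisfy `start <= summit < end`.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open bounds, `start < end`.
#' @param summit absolute 0-based summit positions or NA.
#' @param score caller scores or NA.
#' @param replicate_id label of the sample that called each peak.
#' @return data.frame of class `chip_peaks` with columns
#'   chrom/start/end/summit/score/replicate_id.
#' @export
peaks <- function(chrom, start, end, summit = NA_real_, score = NA_real_,
                  replicate_id = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    summit = as.numeric(summit),
    score = as.numeric(score),
    replicate_id = as.character(replicate_id),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

#' @rdname peaks
#' @param x a data frame with peak columns.
#' @export
validate_peaks <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (!"summit" %in% names(x)) x$summit <- NA_real_
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"replicate_id" %in% names(x)) x$replicate_id <- NA_character_
  if (nrow(x) > 0) {
    bad <- which(!(x$start < x$end))
    if (length(bad))
      stop("peak(s) with start >= end at row(s) ", paste(bad, collapse = ", "))
    has_smt <- !is.na(x$summit)
    bad <- which(has_smt & !(x$summit >= x$start & x$summit < x$end))
    if (length(bad))
      stop("summit outside [start, end) at row(s) ", paste(bad, collapse = ", "))
  }
  class(x) <- unique(c("chip_peaks", class(x)))
  x
}

#' Construct an aligned-read table
#'
#' One row per uniquely mapped read: 0-based half-open interval plus strand.
#' Strand must be "+" or "-"; reads are the quantification currency for PBC,
#' FRIP, cross-correlation and RPKM.
#'
#' @param chrom,start,end as in [peaks()].
#' @param strand "+" or "-".
#' @return data.frame of class `chip_reads`.
#' @export
reads <- function(chrom, start, end, strand) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_reads(df)
}

#' @rdname reads
#' @param x a data frame with read columns.
#' @export
validate_reads <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (nrow(x) > 0) {
    if (any(x$start >= x$end)) stop("read with start >= end")
    bad <- which(!x$strand %in% c("+", "-"))
    if (length(bad))
      stop("invalid strand (must be + or -) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  class(x) <- unique(c("chip_reads", class(x)))
  x
}

#' Construct a gene-model table
#'
#' @param gene_id identifiers.
#' @param chrom,start,end 0-based half-open gene span.
#' @param strand "+" or "-".
#' @return data.frame of class `chip_genes`.
#' @export
genes <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    if (any(df$start >= df$end)) stop("gene with start >= end")
    if (any(!df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  }
  class(df) <- unique(c("chip_genes", class(df)))
  df
}

#' Chromosome sizes
#'
#' @param sizes named numeric vector, chromosome name -> length in bp.
#' @return named numeric vector validated to have positive lengths.
#' @export
chrom_sizes <- function(sizes) {
  if (is.data.frame(sizes)) sizes <- stats::setNames(sizes[[2]], sizes[[1]])
  sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all chromosome lengths must be positive")
  sizes
}

# GRanges from a 0-based half-open table (IRanges is 1-based closed).
as_gr <- function(df, strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (strand && "strand" %in% names(df)) df$strand else "*"
  )
}

# sort a coordinate table by (chrom, start, end); stable
sort_coords <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
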