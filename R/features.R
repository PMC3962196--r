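#' Promoter regions around transcription start sites
#'
#' The TSS is the gene start on the plus strand and `end - 1` on the minus
#' strand; the promoter is `[TSS - flank, TSS + flank)`, clipped to the
#' chromosome. Genes on chromosomes absent from `sizes` are skipped with a
#' warning.
#'
#' @param gns a `chip_genes` data frame.
#' @param sizes chromosome sizes.
#' @param flank bp either side of the TSS (default 2000).
#' @return data frame: feature_id, kind ("promoter"), chrom, start, end,
#'   source_gene, strand; `group_id` duplicates feature_id so the table
#'   plugs directly into [quantify()].
#' @export
make_promoters <- function(gns, sizes, flank = 2000) {
  feature_regions(gns, sizes, flank, kind = "promoter")
}

#' Genic regions with flanks
#'
#' The gene span extended by `flank` bp upstream of the TSS and downstream
#' of the transcript termination site. With symmetric flanks this is
#' `[start - flank, end + flank)` for either strand; strand is retained.
#'
#' @inheritParams make_promoters
#' @return as [make_promoters()], kind "genic".
#' @export
make_genic <- function(gns, sizes, flank = 2000) {
  feature_regions(gns, sizes, flank, kind = "genic")
}

feature_regions <- function(gns, sizes, flank, kind) {
  sizes <- chrom_sizes(sizes)
  known <- gns$chrom %in% names(sizes)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on unknown chromosomes skipped")
    gns <- gns[known, , drop = FALSE]
  }
  if (nrow(gns) == 0) {
    out <- data.frame(feature_id = character(), kind = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), source_gene = character(),
                      strand = character(), group_id = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  clen <- sizes[gns$chrom]
  if (kind == "promoter") {
    tss <- ifelse(gns$strand == "+", gns$start, gns$end - 1)
    start <- tss - flank; end <- tss + flank
  } else {
    start <- gns$start - flank; end <- gns$end + flank
  }
  start <- pmax(0, start); end <- pmin(clen, end)
  out <- data.frame(
    feature_id = paste0(kind, ":", gns$gene_id), kind = kind,
    chrom = gns$chrom, start = start, end = end,
    source_gene = gns$gene_id, strand = gns$strand,
    stringsAsFactors = FALSE)
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$group_id <- out$feature_id
  rownames(out) <- NULL
  out
}

#' Quantify reads over annotation-derived features
#'
#' Peak-calling-independent quantification: RPKM of each promoter or genic
#' region in each replicate, via [quantify()].
#'
#' @param features output of [make_promoters()] or [make_genic()].
#' @param read_sets named list of `chip_reads`.
#' @param totals total mapped reads per replicate (default `nrow`).
#' @return a `coverage_matrix`.
#' @export
quantify_features <- function(features, read_sets, totals = NULL) {
  if (nrow(features) == 0) {
    m <- matrix(numeric(), nrow = 0, ncol = length(read_sets),
                dimnames = list(NULL, names(read_sets)))
    return(structure(list(regions = features, rpkm = m, counts = m,
                          totals = totals), class = "coverage_matrix"))
  }
  quantify(features, read_sets, totals)
}
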