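#' Run the full replicate-QC pipeline
#'
#' End-to-end orchestration: per-replicate QC (PBC, FRIP; NSC/RSC when a
#' read length is given), cross-replicate peak grouping and classification
#' with pairwise agreement, consensus-region building, RPKM quantification,
#' DABG rescue screening of dropout replicates, concordance statistics, and
#' (when an annotation is supplied) promoter/genic feature quantification.
#' QC thresholds (PBC 0.7, kappa 0.75, alpha 0.05) only flag; they never
#' fail the run.
#'
#' @param peak_files named character vector of per-replicate peak files.
#' @param read_files named character vector of per-replicate read BEDs
#'   (same names as `peak_files`).
#' @param chrom_sizes_file two-column chrom/length TSV.
#' @param out_dir output directory for the per-stage TSVs + JSON summary.
#' @param dialect peak-file dialect, "bed6" or "narrowPeak".
#' @param annotation_file optional GFF3/GTF for feature-based QC.
#' @param method consensus definition (default "MAX").
#' @param footprint,avg_width bp, for ASF/ASW.
#' @param alpha DABG significance level.
#' @param read_length optional; enables NSC/RSC.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(peak_files, read_files, chrom_sizes_file, out_dir,
                         dialect = "bed6", annotation_file = NULL,
                         method = "MAX", footprint = NULL, avg_width = NULL,
                         alpha = 0.05, read_length = NULL) {
  labels <- names(peak_files)
  if (is.null(labels) || anyDuplicated(labels))
    stop("peak_files must be uniquely named by replicate")
  if (!identical(sort(labels), sort(names(read_files))))
    stop("read_files labels must match peak_files labels")
  if (length(labels) < 2) stop("need >= 2 replicates")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sizes <- stage("input", read_chrom_sizes(chrom_sizes_file))
  peak_sets <- stage("input", stats::setNames(lapply(labels, function(l)
    read_peaks(peak_files[[l]], dialect, replicate_id = l)), labels))
  read_sets <- stage("input", stats::setNames(lapply(labels, function(l)
    read_reads(read_files[[l]])), labels))

  qc1 <- stage("qc1", do.call(rbind, lapply(labels, function(l)
    qc_report(read_sets[[l]], peak_sets[[l]], l, read_length))))
  write_table(qc1, file.path(out_dir, "qc1.tsv"))

  groups <- stage("overlap", classify_groups(group_peaks(peak_sets)))
  write_table(groups$groups, file.path(out_dir, "groups.tsv"))
  agree <- stage("overlap", pairwise_agreement(peak_sets))
  write_table(agree, file.path(out_dir, "pairwise_agreement.tsv"))

  cons <- stage("consensus", build_consensus(
    groups, method, sizes, footprint = footprint, avg_width = avg_width))
  write_regions(cons, file.path(out_dir, "consensus.bed"))

  totals <- vapply(read_sets, nrow, numeric(1))
  cov <- stage("quantify", quantify(cons, read_sets, totals))
  write_table(cbind(cons[c("group_id", "chrom", "start", "end")],
                    as.data.frame(cov$rpkm)),
              file.path(out_dir, "coverage_rpkm.tsv"))

  peak_rpkms <- stage("dabg", stats::setNames(lapply(labels, function(l) {
    own <- peak_sets[[l]]
    if (nrow(own) == 0) return(numeric())
    own$group_id <- sprintf("own_%05d", seq_len(nrow(own)))
    quantify(own, read_sets[l], totals[l])$rpkm[, 1]
  }), labels))
  dabg_res <- stage("dabg",
                    dabg_screen(groups, cov, peak_rpkms, alpha = alpha))
  write_table(dabg_res, file.path(out_dir, "dabg.tsv"))

  conc <- stage("concordance", concordance_report(cov))
  write_table(conc, file.path(out_dir, "concordance.tsv"))

  features <- NULL
  if (!is.null(annotation_file)) {
    gns <- stage("features", read_annotation(annotation_file))
    prom <- make_promoters(gns, sizes)
    genic <- make_genic(gns, sizes)
    fcov <- stage("features", quantify_features(prom, read_sets, totals))
    write_table(cbind(prom[c("feature_id", "chrom", "start", "end")],
                      as.data.frame(fcov$rpkm)),
                file.path(out_dir, "promoter_rpkm.tsv"))
    features <- list(promoters = prom, genic = genic, coverage = fcov)
  }

  summary <- list(
    n_replicates = length(labels),
    replicates = labels,
    class_counts = as.list(groups$class_counts),
    qc_flags = list(
      pbc_below_0.7 = qc1$replicate_id[!qc1$pbc_ok],
      kappa_below_0.75 = conc$rep_a[!conc$kappa_excellent]
    ),
    dabg_confirmation_rates = as.list(attr(dabg_res, "confirmation_rates")),
    consensus_method = method
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(qc1 = qc1, groups = groups, agreement = agree,
                 consensus = cons, coverage = cov, dabg = dabg_res,
                 concordance = conc, features = features,
                 summary = summary))
}
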