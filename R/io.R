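#' Read peak calls from BED6 or narrowPeak
#'
#' All coordinates are kept 0-based half-open, BED's native convention.
#' For narrowPeak the 10th column (summit offset from `start`; -1 when the
#' caller reported none) is converted to an absolute position on ingest, so
#' downstream code never sees offsets.
#'
#' @param path BED6 or ENCODE narrowPeak file.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @param replicate_id label attached to every peak; defaults to the file
#'   base name without extension.
#' @return a `chip_peaks` data frame sorted by (chrom, start, end).
#' @export
read_peaks <- function(path, dialect = c("bed6", "narrowPeak"),
                       replicate_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(replicate_id))
    replicate_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(validate_peaks(peaks(character(), numeric(), numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "narrowPeak") 10L else 3L
  n_fields <- lengths(fields)
  bad <- which(n_fields < need)
  if (length(bad))
    stop("malformed ", dialect, " line ", bad[1], " in ", path,
         ": expected >= ", need, " columns, got ", n_fields[bad[1]])
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(need)]))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed coordinates on line ", bad[1], " in ", path)
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end on line ", bad[1], " in ", path)
  score <- if (need >= 5L) suppressWarnings(as.numeric(m[, 5])) else NA_real_
  if (dialect == "narrowPeak") {
    off <- suppressWarnings(as.numeric(m[, 10]))
    bad <- which(is.na(off))
    if (length(bad)) stop("malformed summit offset on line ", bad[1])
    summit <- ifelse(off < 0, NA_real_, start + off)
    bad <- which(!is.na(summit) & (summit < start | summit >= end))
    if (length(bad))
      stop("summit outside [start, end) on line ", bad[1], " in ", path)
  } else {
    summit <- NA_real_
  }
  df <- peaks(m[, 1], start, end, summit, score, replicate_id)
  sort_coords(df)
}

#' Read aligned-read positions from BED
#'
#' Requires >= 6 columns; strand is column 6 and must be "+" or "-".
#'
#' @param path BED file of read alignments.
#' @return a `chip_reads` data frame sorted by (chrom, start).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(reads(character(), numeric(), numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop("read BED needs >= 6 columns; line ", bad[1], " in ", path)
  m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand '", strand[bad[1]], "' on line ", bad[1], " in ", path)
  df <- reads(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), strand)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read gene models from GFF3/GTF
#'
#' Keeps rows whose feature type (column 3) matches `feature`, and converts
#' GFF 1-based inclusive coordinates to 0-based half-open. The gene id is the
#' `ID=`/`gene_id` attribute when present, else a positional id.
#'
#' @param path GFF3 or GTF file.
#' @param feature feature type to keep (default `"gene"`).
#' @return a `chip_genes` data frame.
#' @export
read_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == feature,
                 logical(1))
  fields <- fields[keep]
  if (!length(fields))
    return(genes(character(), character(), numeric(), numeric(), character()))
  m <- do.call(rbind, lapply(fields, function(f) f[c(1, 4, 5, 7, 9)]))
  strand <- m[, 4]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("gene with missing/invalid strand '", strand[bad[1]],
         "' in ", path)
  ids <- vapply(seq_len(nrow(m)), function(i) {
    attr <- m[i, 5]
    hit <- regmatches(attr, regexec("(?:^|;)\\s*ID=([^;]+)", attr))[[1]]
    if (length(hit) == 2) return(hit[2])
    hit <- regmatches(attr, regexec("gene_id[= ]\"?([^\";]+)\"?", attr))[[1]]
    if (length(hit) == 2) return(hit[2])
    paste0("gene_", i)
  }, character(1))
  genes(ids, m[, 1],
        as.numeric(m[, 2]) - 1,   # 1-based inclusive -> 0-based half-open
        as.numeric(m[, 3]),
        strand)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name, length.
#' @return named numeric vector (see [chrom_sizes()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  chrom_sizes(stats::setNames(df$size, df$chrom))
}

#' Write intervals as BED6
#'
#' Lossless on coordinates: `read_peaks(write_regions(x))` reproduces the
#' (chrom, start, end) triples exactly.
#'
#' @param regions data frame with chrom/start/end; optional `name`, `score`,
#'   `strand` columns fill BED columns 4-6 (defaults ".", 0, ".").
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(TRUE))
  }
  nm <- if ("name" %in% names(regions)) regions$name else
    if ("group_id" %in% names(regions)) regions$group_id else "."
  sc <- if ("score" %in% names(regions) && !all(is.na(regions$score)))
    ifelse(is.na(regions$score), 0, regions$score) else 0
  st <- if ("strand" %in% names(regions)) regions$strand else "."
  out <- data.frame(regions$chrom, format_bp(regions$start),
                    format_bp(regions$end), nm, sc, st)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(ok)
}

#' Write a TSV table with header
#'
#' @param rows data frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(TRUE)
}

# integer-style formatting for bp coordinates (avoids 1e+05 notation)
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
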