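# Interval arithmetic, BED/TSV readers and writers, multiple-testing
# correction and DEG labeling shared by all pipeline stages.

#' Read a BED file of intervals or peaks
#'
#' Parses a 3-5 column BED file into a peak table. Coordinates are kept in the
#' native BED convention: 0-based, half-open `[start, end)`. An optional 4th
#' column is taken as the record name and an optional 5th column as a
#' non-negative signal value (aggregate enrichment for peak calls).
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `signal`, one row per input line, in file order. `name` defaults to
#'   `peak_<i>` and `signal` to `NA` when the columns are absent.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tp1\t5.0", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), signal = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    .stopf("malformed BED line %d: fewer than 3 tab-separated columns",
           which(nf < 3L)[1L])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) .stopf("malformed BED line %d: non-numeric coordinates", bad[1L])
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    .stopf("invalid interval on line %d: need 0 <= start < end, got [%d, %d)",
           bad[1L], start[bad[1L]], end[bad[1L]])
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 paste0("peak_", seq_along(fields)))
  signal <- rep(NA_real_, length(fields))
  has5 <- nf >= 5L
  signal[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  if (any(!is.na(signal) & signal < 0)) {
    .stopf("negative signal on line %d", which(!is.na(signal) & signal < 0)[1L])
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             signal = signal)
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` plus `name` and
#' `signal` columns when present. Integer coordinates round-trip exactly.
#'
#' @param x Interval `data.frame` with at least `chrom`, `start`, `end`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "signal"), names(x))
  out <- x[, cols, drop = FALSE]
  if ("signal" %in% cols && all(is.na(out$signal))) out$signal <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Partition two interval sets into common and specific intervals
#'
#' Reproduces the replicate/condition peak comparison used to define
#' "convincing" and condition-specific peaks: an interval is *common* iff it
#' overlaps at least one interval of the other set by at least `min_overlap`
#' bases; otherwise it is *specific*. The partition is exhaustive and disjoint
#' within each set.
#'
#' @param set_a,set_b Interval `data.frame`s (`chrom`, `start`, `end`, ...).
#' @param min_overlap Minimum shared bases to count as an overlap (default 1).
#' @return A list with elements `common_a`, `specific_a`, `common_b`,
#'   `specific_b`, each a row-subset of the corresponding input.
#' @export
overlap_partition <- function(set_a, set_b, min_overlap = 1L) {
  if (length(min_overlap) != 1L || is.na(min_overlap) || min_overlap < 1) {
    .stopf("min_overlap must be a positive integer")
  }
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) {
    return(list(common_a = set_a[0L, ], specific_a = set_a,
                common_b = set_b[0L, ], specific_b = set_b))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(set_a), .as_granges(set_b),
                                      minoverlap = as.integer(min_overlap))
  in_a <- seq_len(nrow(set_a)) %in% S4Vectors::queryHits(hits)
  in_b <- seq_len(nrow(set_b)) %in% S4Vectors::subjectHits(hits)
  list(common_a = set_a[in_a, , drop = FALSE],
       specific_a = set_a[!in_a, , drop = FALSE],
       common_b = set_b[in_b, , drop = FALSE],
       specific_b = set_b[!in_b, , drop = FALSE])
}

#' Distance from each peak to the nearest transcription start site
#'
#' For each peak, the absolute distance from the peak midpoint
#' (`floor((start + end) / 2)`) to the closest TSS on the same chromosome.
#' Used to show that condition-specific enhancer peaks sit farther from
#' promoters than shared ones.
#'
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`).
#' @param genes Gene table with columns `chrom` and `tss`.
#' @return Integer vector of distances, one per peak, in input order.
#' @export
nearest_tss_distance <- function(peaks, genes) {
  missing <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(missing)) {
    .stopf("no genes on chromosome(s) carrying peaks: %s",
           paste(missing, collapse = ", "))
  }
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- integer(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    out[pk] <- vapply(mid[pk], function(m) min(abs(tss - m)), 0L)
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#' Thin validated wrapper over the standard step-up implementation so that
#' every stage of the pipeline adjusts p-values through one entry point.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    .stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Label differentially expressed genes from a DE table
#'
#' Applies the study's DEG rule: `up` iff `log2fc > lfc_threshold` and
#' `padj < padj_threshold`; `down` iff `log2fc < -lfc_threshold` and
#' `padj < padj_threshold`; otherwise `stable`. Both inequalities are strict.
#'
#' @param table Gene `data.frame` with numeric columns `log2fc` and `padj`.
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 0.9).
#' @param padj_threshold Adjusted p-value cutoff (default 0.01).
#' @return The input with a `de_status` factor column
#'   (levels `up`, `down`, `stable`).
#' @export
classify_degs <- function(table, lfc_threshold = 0.9, padj_threshold = 0.01) {
  if (!all(c("log2fc", "padj") %in% names(table))) {
    .stopf("gene table must carry 'log2fc' and 'padj' columns")
  }
  if (lfc_threshold <= 0 || padj_threshold <= 0) {
    .stopf("thresholds must be positive")
  }
  lfc <- table$log2fc
  padj <- table$padj
  if (anyNA(lfc) || anyNA(padj)) .stopf("log2fc/padj contain missing values")
  status <- rep("stable", nrow(table))
  status[lfc > lfc_threshold & padj < padj_threshold] <- "up"
  status[lfc < -lfc_threshold & padj < padj_threshold] <- "down"
  table$de_status <- factor(status, levels = c("up", "down", "stable"))
  table
}

#' Read / write a gene table (TSV with header)
#'
#' @param path File path.
#' @return For `read_gene_table`, a `data.frame`; column types are as stored.
#' @export
read_gene_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_gene_table
#' @param x Gene `data.frame` to write.
#' @export
write_gene_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
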