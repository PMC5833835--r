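# Bridge-linker read trimming, duplicate removal, strand-based span-threshold
# estimation, and read-pair classification.

#' Bridge-linker configuration
#'
#' The biotinylated bridge linker marks the ligation junction inside a read;
#' the two defaults are the two orientations in which it can appear.
#'
#' @param forward,reverse Linker sequence in each orientation.
#' @param max_mismatches Mismatches tolerated in the linker match (default 0,
#'   exact).
#' @param min_fragment Minimum kept 5' fragment length in bp; shorter
#'   fragments are flagged discarded (mappability floor).
#' @return A list of class `LinkerConfig`.
#' @export
linker_config <- function(forward = "CGCGATATCTTATCTGACT",
                          reverse = "GTCAGATAAGATATCGCGT",
                          max_mismatches = 0L,
                          min_fragment = 20L) {
  if (!nzchar(forward) || !nzchar(reverse)) .stopf("linker sequences must be non-empty")
  if (max_mismatches < 0) .stopf("max_mismatches must be >= 0")
  structure(list(forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches),
                 min_fragment = as.integer(min_fragment)),
            class = "LinkerConfig")
}

#' Trim reads at the bridge linker
#'
#' Searches each read for a full linker copy (either orientation, up to
#' `max_mismatches` mismatches). When the linker splits the read into two
#' non-empty fragments, the 5' fragment is kept; a read without a linker
#' passes through whole. Kept fragments shorter than `min_fragment` (in
#' particular, a linker flush with the read start) are flagged `discarded`
#' rather than raising an error. Qualities, when given, are sliced in
#' register with the sequence.
#'
#' @param reads Character vector of read sequences.
#' @param quals Optional character vector of quality strings, same lengths.
#' @param config A `LinkerConfig`.
#' @return `data.frame` with columns `fragment`, `qual` (if given),
#'   `linker_found`, `discarded`.
#' @export
trim_linker <- function(reads, quals = NULL, config = linker_config()) {
  if (length(reads) == 0L) {
    return(data.frame(fragment = character(), linker_found = logical(),
                      discarded = logical()))
  }
  if (any(!nzchar(reads))) .stopf("reads must be non-empty")
  subj <- Biostrings::DNAStringSet(reads)
  pos_of <- function(pattern) {
    hits <- Biostrings::vmatchPattern(pattern, subj,
                                      max.mismatch = config$max_mismatches)
    starts <- Biostrings::startIndex(hits)
    vapply(starts, function(s) if (is.null(s) || !length(s)) NA_integer_
           else min(s), NA_integer_)
  }
  fw <- pos_of(config$forward)
  rv <- pos_of(config$reverse)
  at <- pmin(fw, rv, na.rm = TRUE)
  at[is.na(fw) & is.na(rv)] <- NA_integer_
  found <- !is.na(at)
  frag <- reads
  frag[found] <- substr(reads[found], 1L, at[found] - 1L)
  out <- data.frame(fragment = frag, linker_found = found,
                    discarded = nchar(frag) < config$min_fragment)
  if (!is.null(quals)) {
    if (any(nchar(quals) != nchar(reads))) {
      .stopf("quality strings must match read lengths")
    }
    q <- quals
    q[found] <- substr(quals[found], 1L, at[found] - 1L)
    out$qual <- q
  }
  out
}

# canonical mate order: (chrom1, pos1) <= (chrom2, pos2)
.canonicalize_pairs <- function(pairs) {
  swap <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, c("chrom1", "pos1", "strand1")]
    pairs[swap, c("chrom1", "pos1", "strand1")] <-
      pairs[swap, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  pairs
}

#' Remove duplicate pairs
#'
#' Pairs identical in both mates' chromosome, position and strand collapse to
#' their first occurrence. Mate order is canonicalized first, so records that
#' differ only by mate swap count as duplicates.
#'
#' @param pairs Aligned-pair table (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`).
#' @return Deduplicated, canonicalized pair table.
#' @export
dedupe_pairs <- function(pairs) {
  pairs <- .canonicalize_pairs(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Estimate the short-range span threshold from strand orientation
#'
#' Religation artifacts (unligated full segments, self-ligations) are
#' confined to short spans and have fixed strand geometry, so below the
#' artifact scale the four orientation classes (++, +-, -+, --) are
#' unbalanced. Spans are binned on a log scale; the estimate is the left
#' edge of the smallest informative bin (>= `min_count` pairs) whose four
#' orientation fractions are all within `tolerance` of 0.25.
#'
#' @param pairs Aligned-pair table; only intra-chromosomal pairs are used.
#' @param tolerance Allowed deviation of each orientation fraction from 0.25.
#' @param fallback Returned (with a warning) when there are too few pairs or
#'   no bin qualifies; 3000 bp is the expected scale for a 4-cutter library.
#' @param n_bins Number of log-spaced span bins.
#' @param min_count Minimum pairs per bin for the bin to be informative.
#' @return Span threshold in bp.
#' @export
estimate_span_threshold <- function(pairs, tolerance = 0.05, fallback = 3000L,
                                    n_bins = 30L, min_count = 100L) {
  pairs <- .canonicalize_pairs(pairs)
  intra <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  if (nrow(intra) < 1000L) {
    .warnf("only %d intra-chromosomal pairs; returning fallback threshold %d",
           nrow(intra), fallback)
    return(fallback)
  }
  span <- intra$pos2 - intra$pos1
  span <- pmax(span, 1L)
  orient <- paste0(intra$strand1, intra$strand2)
  edges <- exp(seq(log(max(1, min(span))), log(max(span) + 1),
                   length.out = n_bins + 1L))
  bin <- findInterval(span, edges, rightmost.closed = TRUE)
  informative <- tabulate(bin, n_bins) >= min_count
  balanced <- vapply(seq_len(n_bins), function(b) {
    o <- orient[bin == b]
    if (length(o) < min_count) return(FALSE)
    fr <- table(factor(o, levels = c("++", "+-", "-+", "--"))) / length(o)
    all(abs(fr - 0.25) <= tolerance)
  }, TRUE)
  hit <- which(informative & balanced)
  if (!length(hit)) {
    .warnf("no span bin reaches orientation balance; returning fallback %d",
           fallback)
    return(fallback)
  }
  as.integer(round(edges[hit[1L]]))
}

#' Classify read pairs by span and strand geometry
#'
#' Pairs on different chromosomes are inter-chromosomal ligations. Same
#' chromosome with span at or above the threshold: intra-chromosomal
#' ligation. Below the threshold the strand geometry decides: inward
#' (upstream mate `+`, downstream `-`) pairs are unligated full segments,
#' outward pairs are self-ligations, and same-strand pairs (which require a
#' ligation event) count as intra-chromosomal ligations.
#'
#' @param pairs Aligned-pair table.
#' @param threshold Span threshold in bp (see [estimate_span_threshold()]).
#' @return The canonicalized table with a `class` column (one of
#'   `full_segment`, `self_ligation`, `intra`, `inter`).
#' @export
classify_pairs <- function(pairs, threshold = 3000L) {
  if (threshold <= 0) .stopf("threshold must be positive")
  pairs <- .canonicalize_pairs(pairs)
  span <- pairs$pos2 - pairs$pos1
  cls <- rep("intra", nrow(pairs))
  diff_chrom <- pairs$chrom1 != pairs$chrom2
  cls[diff_chrom] <- "inter"
  short <- !diff_chrom & span < threshold
  cls[short & pairs$strand1 == "+" & pairs$strand2 == "-"] <- "full_segment"
  cls[short & pairs$strand1 == "-" & pairs$strand2 == "+"] <- "self_ligation"
  pairs$class <- cls
  pairs
}

#' Pair classification report
#'
#' Counts and fractions per class, the library-statistics summary mirrored by
#' the pipeline's text output.
#'
#' @param classified Output of [classify_pairs()].
#' @return `data.frame` with `class`, `count`, `fraction`.
#' @export
pair_class_stats <- function(classified) {
  tb <- table(factor(classified$class,
                     levels = c("full_segment", "self_ligation",
                                "intra", "inter")))
  data.frame(class = names(tb), count = as.integer(tb),
             fraction = as.numeric(tb) / max(1L, nrow(classified)))
}
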