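# Gene-region / regulatory-region bin annotation, within-TAD candidate pair
# extraction, and the MA-plot binomial random-sampling differential test.

#' Annotate bins as gene regions and regulatory regions
#'
#' A bin is a *gene region* when a promoter-mark peak midpoint lies within
#' `promoter_window` bp of an expressed gene's TSS and inside the bin; it is
#' a *regulatory region* when a distal-mark peak midpoint lies in the bin and
#' outside every expressed gene's promoter window. A bin can be both. Each
#' bin is assigned to the TAD containing its midpoint (or none).
#'
#' @param bins Bin table from [bin_table()].
#' @param promoter_peaks Promoter-mark (e.g. H3K4me3) peak table.
#' @param distal_peaks Distal acetylation (e.g. H3K27ac) peak table.
#' @param genes Gene table with `chrom`, `tss` and `expressed`.
#' @param tads TAD interval table.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 2000).
#' @return `data.frame` per bin: `index`, `chrom`, `start`, `end`,
#'   `gene_region`, `regulatory_region`, `tad_id`, `linked_genes`,
#'   `linked_peaks` (comma-separated ids).
#' @export
annotate_bins <- function(bins, promoter_peaks, distal_peaks, genes, tads,
                          promoter_window = 2000L) {
  expressed <- genes[genes$expressed, , drop = FALSE]
  out <- bins[, c("index", "chrom", "start", "end")]
  out$gene_region <- FALSE
  out$regulatory_region <- FALSE
  out$linked_genes <- ""
  out$linked_peaks <- ""
  out$tad_id <- .assign_bins_to_tads(bins, tads)

  bin_of <- function(chrom, pos) {
    idx <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      bsel <- which(bins$chrom == ch)
      k <- findInterval(pos[sel], bins$start[bsel])
      valid <- k >= 1L & k <= length(bsel) & pos[sel] < bins$end[bsel[pmax(k, 1L)]]
      idx[sel[valid]] <- bsel[k[valid]]
    }
    idx
  }

  near_tss <- function(chrom, pos) {
    # TRUE where pos is within the promoter window of an expressed TSS
    hit <- logical(length(pos))
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      tss <- expressed$tss[expressed$chrom == ch]
      if (!length(tss)) next
      hit[sel] <- vapply(pos[sel],
                         function(p) any(abs(tss - p) <= promoter_window),
                         TRUE)
    }
    hit
  }

  if (nrow(promoter_peaks)) {
    mid <- (promoter_peaks$start + promoter_peaks$end) %/% 2L
    prom <- near_tss(promoter_peaks$chrom, mid)
    pb <- bin_of(promoter_peaks$chrom, mid)
    for (k in which(prom & !is.na(pb))) {
      b <- pb[k]
      out$gene_region[b] <- TRUE
      out$linked_peaks[b] <- paste(c(strsplit(out$linked_peaks[b], ",")[[1L]],
                                     promoter_peaks$name[k]), collapse = ",")
      tss <- expressed$tss[expressed$chrom == promoter_peaks$chrom[k]]
      ids <- expressed$gene_id[expressed$chrom == promoter_peaks$chrom[k]]
      near <- ids[abs(tss - mid[k]) <= promoter_window]
      out$linked_genes[b] <- paste(
        unique(c(strsplit(out$linked_genes[b], ",")[[1L]], near)),
        collapse = ",")
    }
  }
  if (nrow(distal_peaks)) {
    mid <- (distal_peaks$start + distal_peaks$end) %/% 2L
    distal <- !near_tss(distal_peaks$chrom, mid)
    db <- bin_of(distal_peaks$chrom, mid)
    for (k in which(distal & !is.na(db))) {
      b <- db[k]
      out$regulatory_region[b] <- TRUE
      out$linked_peaks[b] <- paste(c(strsplit(out$linked_peaks[b], ",")[[1L]],
                                     distal_peaks$name[k]), collapse = ",")
    }
  }
  out$linked_genes <- sub("^,", "", out$linked_genes)
  out$linked_peaks <- sub("^,", "", out$linked_peaks)
  out
}

#' Extract within-TAD gene-regulatory candidate pairs
#'
#' One candidate per ordered (gene-region bin, regulatory-region bin) pair
#' sharing a TAD, with distinct bin indices. Counts are pooled over the
#' replicates of each condition; pairs whose pooled counts fall below
#' `min_total` are dropped (the normal approximation of the test needs a
#' minimum count). The per-condition sampling totals `n1`, `n2` (total
#' intra-chromosomal mass, pooled over replicates) are attached as
#' attributes.
#'
#' @param annotations Output of [annotate_bins()].
#' @param cond1,cond2 Lists of `ContactMatrix` replicates per condition.
#' @param min_total Minimum `C1 + C2` (default 10).
#' @return `data.frame` (`gene_bin`, `reg_bin`, `tad_id`, `linked_genes`,
#'   `C1`, `C2`) with attributes `n1`, `n2`.
#' @export
extract_candidate_pairs <- function(annotations, cond1, cond2,
                                    min_total = 10L) {
  pool <- function(reps) Reduce(`+`, lapply(reps, `[[`, "counts"))
  M1 <- pool(cond1)
  M2 <- pool(cond2)
  n1 <- sum(vapply(cond1, matrix_mass, 0, intra_only = TRUE))
  n2 <- sum(vapply(cond2, matrix_mass, 0, intra_only = TRUE))
  rows <- list()
  ann <- annotations[!is.na(annotations$tad_id), ]
  for (tid in unique(ann$tad_id)) {
    sub <- ann[ann$tad_id == tid, ]
    gb <- sub$index[sub$gene_region]
    rb <- sub$index[sub$regulatory_region]
    if (!length(gb) || !length(rb)) next
    grid <- expand.grid(gene_bin = gb, reg_bin = rb)
    grid <- grid[grid$gene_bin != grid$reg_bin, , drop = FALSE]
    if (!nrow(grid)) next
    grid$tad_id <- tid
    rows[[tid]] <- grid
  }
  if (!length(rows)) {
    .warnf("no within-TAD gene-regulatory candidate pairs found")
    out <- data.frame(gene_bin = integer(), reg_bin = integer(),
                      tad_id = character(), linked_genes = character(),
                      C1 = numeric(), C2 = numeric())
    attr(out, "n1") <- n1; attr(out, "n2") <- n2
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$linked_genes <- annotations$linked_genes[match(out$gene_bin,
                                                     annotations$index)]
  out$C1 <- M1[cbind(out$gene_bin, out$reg_bin)]
  out$C2 <- M2[cbind(out$gene_bin, out$reg_bin)]
  dropped <- out$C1 + out$C2 < min_total
  if (any(dropped)) {
    message(sprintf("dropping %d candidate pair(s) below the minimum count of %d",
                    sum(dropped), min_total))
  }
  out <- out[!dropped, , drop = FALSE]
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

#' MA-plot binomial random-sampling differential test
#'
#' Models the counts of one interaction in the two conditions as
#' `Ci ~ Binomial(ni, pi)` and tests `H0: p1 = p2`. With `X = log2 C1`,
#' `Y = log2 C2`, `M = Y - X` (oriented condition 2 minus condition 1, so
#' gains are positive) and `A = (X + Y) / 2`, the conditional distribution
#' of `M` given `A = a` is approximately normal under H0. The common
#' sampling probability is estimated from the observed `a` as
#' `p = 2^a / sqrt(n1 n2)`; the delta method gives
#' `Var(X) = (1 - p) / (n1 p ln2^2)` (and symmetrically for `Y`), hence the
#' conditional mean `log2(n2 / n1)` and conditional variance
#' `4 Var(X) Var(Y) / (Var(X) + Var(Y))`, from which the z score and the
#' two-sided normal p-value follow.
#'
#' @param C1,C2 Positive counts per interaction (condition 1 / condition 2),
#'   vectorized.
#' @param n1,n2 Total Hi-C counts per condition.
#' @return `data.frame` with `C1`, `C2`, `M`, `A`, `p1_hat`, `p2_hat`, `z`,
#'   `p`.
#' @export
mars_test <- function(C1, C2, n1, n2) {
  if (any(C1 < 1) || any(C2 < 1)) {
    .stopf("counts must be >= 1 (zero-count pairs are filtered upstream)")
  }
  if (n1 <= 0 || n2 <= 0) .stopf("totals must be positive")
  X <- log2(C1)
  Y <- log2(C2)
  M <- Y - X
  A <- (X + Y) / 2
  phat <- 2^A / sqrt(n1 * n2)
  if (any(phat >= 1) || any(phat <= 0)) {
    .stopf("estimated sampling probability outside (0, 1); counts inconsistent with totals")
  }
  ln2sq <- log(2)^2
  vx <- (1 - phat) / (n1 * phat * ln2sq)
  vy <- (1 - phat) / (n2 * phat * ln2sq)
  cond_var <- 4 * vx * vy / (vx + vy)
  z <- (M - log2(n2 / n1)) / sqrt(cond_var)
  data.frame(C1 = C1, C2 = C2, M = M, A = A,
             p1_hat = C1 / n1, p2_hat = C2 / n2,
             z = z, p = 2 * pnorm(-abs(z)))
}

#' Call Gain and Loss interactions
#'
#' BH-adjusts the batch of MA-test p-values and calls *Gain* where
#' `p_adj < threshold` and the condition-2 count proportion exceeds the
#' condition-1 proportion (*Loss* symmetric; everything else `NS`). Also
#' returns the unique genes linked to the gene bins of each call set.
#'
#' @param results `data.frame` combining candidate pairs and [mars_test()]
#'   columns (needs `p`, `p1_hat`, `p2_hat`, optionally `linked_genes`).
#' @param threshold Adjusted-p cutoff (default 0.001).
#' @return The input with `p_adj` and `call` columns, plus attributes
#'   `gain_genes` and `loss_genes`.
#' @export
call_gain_loss <- function(results, threshold = 0.001) {
  if (!all(c("p", "p1_hat", "p2_hat") %in% names(results))) {
    .stopf("results must carry 'p', 'p1_hat' and 'p2_hat' columns")
  }
  if (nrow(results) == 0L) {
    results$p_adj <- numeric()
    results$call <- character()
    return(results)
  }
  results$p_adj <- bh_adjust(results$p)
  call <- rep("NS", nrow(results))
  call[results$p_adj < threshold & results$p2_hat > results$p1_hat] <- "Gain"
  call[results$p_adj < threshold & results$p2_hat < results$p1_hat] <- "Loss"
  results$call <- factor(call, levels = c("Gain", "Loss", "NS"))
  genes_of <- function(sel) {
    if (is.null(results$linked_genes)) return(character())
    unique(unlist(strsplit(results$linked_genes[sel], ",")))
  }
  attr(results, "gain_genes") <- genes_of(results$call == "Gain")
  attr(results, "loss_genes") <- genes_of(results$call == "Loss")
  results
}
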