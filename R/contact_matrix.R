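# Binned contact matrices: construction from classified pairs, iterative
# correction (ICE), observed/expected transform, replicate reproducibility.

#' Genome bin table
#'
#' Tiles each chromosome with fixed-size bins. The last bin of a chromosome is
#' truncated at the chromosome end. Bins carry a global 1-based `index` used
#' as the row/column index of contact matrices.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `index`.
#' @export
bin_table <- function(chrom_sizes, bin_size) {
  if (bin_size <= 0) .stopf("bin_size must be positive")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    .stopf("chrom_sizes must be a named vector")
  }
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, len)))
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  out
}

#' Construct a ContactMatrix
#'
#' A symmetric, non-negative, genome-wide binned count matrix together with
#' its bin table, optional per-bin balancing weights, and free-form metadata
#' (sample / condition / replicate labels). Stored dense; at the scales this
#' package targets (a few thousand bins) that is the simplest faithful
#' representation.
#'
#' @param counts Square symmetric numeric matrix, `nrow == nrow(bins)`.
#' @param bins Bin table from [bin_table()].
#' @param bin_size Bin width in bp.
#' @param weights Optional per-bin positive balancing weights (`NA` = masked).
#' @param metadata Named list of labels.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, bins, bin_size, weights = NULL,
                           metadata = list()) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    .stopf("counts must be a square matrix")
  }
  if (nrow(counts) != nrow(bins)) .stopf("counts and bin table sizes differ")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    .stopf("counts must be symmetric")
  }
  if (!is.null(weights) && length(weights) != nrow(bins)) {
    .stopf("weights length must equal the number of bins")
  }
  structure(list(counts = counts, bins = bins, bin_size = bin_size,
                 weights = weights, metadata = metadata),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins (%d bp), %d chromosome(s), total counts %.0f\n",
              nrow(x$bins), x$bin_size, length(unique(x$bins$chrom)),
              matrix_mass(x)))
  if (!is.null(x$weights)) {
    cat(sprintf("  balanced (%d masked bins)\n", sum(is.na(x$weights))))
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Upper-triangle + diagonal mass; intra_only restricts to same-chromosome cells.
#' Total contact mass of a matrix
#'
#' Sum of counts over the upper triangle including the diagonal, i.e. the
#' number of pairs the matrix represents. With `intra_only = TRUE`, only
#' same-chromosome cells are summed (the "total number of Hi-C counts" used
#' as the sampling total of the differential test).
#'
#' @param m A `ContactMatrix`.
#' @param intra_only Restrict to intra-chromosomal cells?
#' @return A single number.
#' @export
matrix_mass <- function(m, intra_only = FALSE) {
  ut <- upper.tri(m$counts, diag = TRUE)
  if (intra_only) {
    same <- outer(m$bins$chrom, m$bins$chrom, "==")
    ut <- ut & same
  }
  sum(m$counts[ut])
}

#' Bin classified pairs into a contact matrix
#'
#' Each kept pair increments its (bin1, bin2) cell and, off the diagonal, the
#' mirror cell. Full-segment and self-ligation artifacts are excluded by
#' default; only `intra` and `inter` ligation products carry conformation
#' signal.
#'
#' @param pairs Classified pair table from [classify_pairs()] (columns
#'   `chrom1`, `pos1`, `chrom2`, `pos2`, `class`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param classes_kept Pair classes that enter the matrix.
#' @param metadata Metadata list passed to the matrix.
#' @return A `ContactMatrix`.
#' @export
bin_pairs_to_matrix <- function(pairs, chrom_sizes, bin_size,
                                classes_kept = c("intra", "inter"),
                                metadata = list()) {
  bins <- bin_table(chrom_sizes, bin_size)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  keep <- pairs$class %in% classes_kept
  kept <- pairs[keep, , drop = FALSE]
  if (nrow(kept)) {
    bad <- !(kept$chrom1 %in% names(chrom_sizes)) |
      !(kept$chrom2 %in% names(chrom_sizes)) |
      kept$pos1 >= chrom_sizes[kept$chrom1] |
      kept$pos2 >= chrom_sizes[kept$chrom2] |
      kept$pos1 < 0 | kept$pos2 < 0
    if (any(bad)) {
      .stopf("pair record %d maps beyond chromosome bounds",
             which(keep)[which(bad)[1L]])
    }
    offset <- setNames(vapply(names(chrom_sizes), function(ch) {
      min(bins$index[bins$chrom == ch]) - 1L
    }, 0L), names(chrom_sizes))
    i <- offset[kept$chrom1] + kept$pos1 %/% bin_size + 1L
    j <- offset[kept$chrom2] + kept$pos2 %/% bin_size + 1L
    for (k in seq_along(i)) {
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
      if (i[k] != j[k]) counts[j[k], i[k]] <- counts[j[k], i[k]] + 1
    }
  }
  contact_matrix(counts, bins, bin_size, metadata = metadata)
}

#' Iterative correction (ICE) balancing
#'
#' Computes per-bin multiplicative weights `w` such that the corrected matrix
#' `counts[i,j] * w[i] * w[j]` has equal row sums over unmasked bins, removing
#' coverage (visibility) biases. The lowest-coverage `mask_low` fraction of
#' bins, and all zero-coverage bins, are masked (`NA` weights) and excluded.
#'
#' @param m A `ContactMatrix`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the max relative row-sum deviation.
#' @param mask_low Fraction of lowest-coverage bins to mask (default 0.02).
#' @return The matrix with a `weights` component filled in.
#' @export
ice_balance <- function(m, max_iter = 200L, tol = 1e-5, mask_low = 0.02) {
  counts <- m$counts
  n <- nrow(counts)
  cov <- rowSums(counts)
  if (all(cov == 0)) .stopf("cannot balance an all-zero matrix")
  masked <- cov == 0
  if (mask_low > 0) {
    thr <- quantile(cov[cov > 0], mask_low)
    masked <- masked | cov <= thr
  }
  keep <- which(!masked)
  w <- rep(NA_real_, n)
  w[keep] <- 1
  sub <- counts[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.vector(sub %*% b) * b
    s <- s / mean(s)
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    b <- b / sqrt(s)
  }
  if (!converged) .warnf("ICE did not converge in %d iterations", max_iter)
  # normalize so corrected total mass matches raw total mass
  w[keep] <- b
  corr <- sub * outer(b, b)
  w[keep] <- b * sqrt(sum(sub) / sum(corr))
  m$weights <- w
  m
}

#' Corrected (balanced) counts
#'
#' Applies the balancing weights: `counts[i,j] * w[i] * w[j]`. Masked rows and
#' columns become `NA`.
#'
#' @param m A balanced `ContactMatrix` (see [ice_balance()]).
#' @return Numeric matrix of corrected counts.
#' @export
corrected_counts <- function(m) {
  if (is.null(m$weights)) .stopf("matrix has no balancing weights; run ice_balance()")
  w <- m$weights
  m$counts * outer(w, w)
}

#' Observed / expected transform
#'
#' Per chromosome, divides the corrected count of each cell by the mean
#' corrected count at its genomic distance (diagonal-wise expectation over
#' unmasked bins). Inter-chromosomal cells, masked bins, and zero-expected
#' diagonals are `NA`.
#'
#' @param m A balanced intra-chromosomal `ContactMatrix`.
#' @return Matrix of O/E ratios with the same dimensions as the counts.
#' @export
oe_transform <- function(m) {
  corr <- corrected_counts(m)
  n <- nrow(corr)
  out <- matrix(NA_real_, n, n)
  for (ch in unique(m$bins$chrom)) {
    idx <- m$bins$index[m$bins$chrom == ch]
    ok <- idx[!is.na(m$weights[idx])]
    if (length(ok) < 2L) .stopf("fewer than 2 unmasked bins on %s", ch)
    sub <- corr[ok, ok, drop = FALSE]
    k <- length(ok)
    d <- abs(outer(seq_len(k), seq_len(k), "-"))
    expd <- tapply(as.vector(sub), as.vector(d), mean)
    E <- matrix(expd[as.character(d)], k, k)
    ratio <- sub / E
    ratio[!is.finite(ratio)] <- NA_real_
    out[ok, ok] <- ratio
  }
  out
}

#' Replicate reproducibility of two contact maps
#'
#' Pearson correlation of `log2(1 + count)` over upper-triangle
#' intra-chromosomal cells after coarsening both maps to `coarsen_to` bins.
#' Coarse (megabase) binning matches the whole-genome heatmap scale at which
#' replicate agreement is judged.
#'
#' @param m1,m2 `ContactMatrix` objects on the same genome and binning.
#' @param coarsen_to Coarse bin width in bp (default 1 Mb).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(m1, m2, coarsen_to = 1e6) {
  if (!identical(dim(m1$counts), dim(m2$counts)) ||
      !identical(m1$bins, m2$bins)) {
    .stopf("matrices are on different genomes or binnings")
  }
  v1 <- .coarsen_upper(m1, coarsen_to)
  v2 <- .coarsen_upper(m2, coarsen_to)
  cor(log2(1 + v1), log2(1 + v2))
}

.coarsen_upper <- function(m, coarsen_to) {
  fac <- max(1L, as.integer(coarsen_to %/% m$bin_size))
  vals <- c()
  for (ch in unique(m$bins$chrom)) {
    idx <- m$bins$index[m$bins$chrom == ch]
    sub <- m$counts[idx, idx, drop = FALSE]
    grp <- (seq_along(idx) - 1L) %/% fac
    agg <- rowsum(t(rowsum(sub, grp)), grp)  # sum into coarse cells
    vals <- c(vals, agg[upper.tri(agg, diag = TRUE)])
  }
  vals
}

#' Write / read a contact matrix as sparse triplets
#'
#' The native text interchange format: a bin table TSV and a 3-column triplet
#' TSV (`bin1`, `bin2`, `count`) listing the non-zero upper-triangle cells.
#'
#' @param m A `ContactMatrix`.
#' @param triplet_path,bins_path Output paths for the two files.
#' @return For the writer, the triplet path invisibly; for the reader,
#'   a `ContactMatrix`.
#' @export
write_matrix_triplets <- function(m, triplet_path, bins_path) {
  write.table(m$bins, bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  trip <- data.frame(bin1 = ut[, 1L], bin2 = ut[, 2L],
                     count = m$counts[ut])
  trip <- trip[order(trip$bin1, trip$bin2), ]
  write.table(trip, triplet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(triplet_path)
}

#' @rdname write_matrix_triplets
#' @param bin_size Bin width in bp (must match the bin table).
#' @export
read_matrix_triplets <- function(triplet_path, bins_path, bin_size) {
  bins <- read.table(bins_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  trip <- read.table(triplet_path, header = TRUE, sep = "\t")
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  counts[cbind(trip$bin1, trip$bin2)] <- trip$count
  counts[cbind(trip$bin2, trip$bin1)] <- trip$count
  contact_matrix(counts, bins, bin_size)
}
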