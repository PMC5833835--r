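# Per-TAD interaction counting, the replicate-derived empirical-null
# fold-change test, sigma-deviation categories, DEG distribution across
# categories, and boundary stability.

#' Per-TAD internal and external interaction counts
#'
#' For each TAD: *internal* is the sum of counts over distinct bin pairs with
#' both bins inside the TAD (the diagonal, dominated by short-range
#' artifacts, is excluded); *external* sums intra-chromosomal cells with
#' exactly one bin inside. Counts are depth-normalized by the matrix's total
#' intra-chromosomal mass so that samples of different depth are comparable;
#' with `normalize = FALSE` the raw sums are returned.
#'
#' @param m A `ContactMatrix`.
#' @param tads TAD interval table (`chrom`, `start`, `end`, optional
#'   `tad_id`), non-overlapping within a chromosome.
#' @param normalize Divide by the total intra-chromosomal mass?
#' @return `data.frame` with `tad_id`, `chrom`, `start`, `end`, `n_bins`,
#'   `internal`, `external`.
#' @export
tad_counts <- function(m, tads, normalize = TRUE) {
  if (is.null(tads$tad_id)) tads$tad_id <- paste0("tad_", seq_len(nrow(tads)))
  tad_of_bin <- .assign_bins_to_tads(m$bins, tads)
  total <- matrix_mass(m, intra_only = TRUE)
  out <- tads[, c("tad_id", "chrom", "start", "end")]
  out$n_bins <- 0L
  out$internal <- 0
  out$external <- 0
  for (k in seq_len(nrow(tads))) {
    inside <- which(tad_of_bin == tads$tad_id[k])
    out$n_bins[k] <- length(inside)
    if (length(inside) < 2L) {
      .warnf("TAD %s spans fewer than 2 bins; internal count set to 0",
             tads$tad_id[k])
      next
    }
    sub <- m$counts[inside, inside, drop = FALSE]
    out$internal[k] <- sum(sub[upper.tri(sub)])
    same_chrom <- which(m$bins$chrom == tads$chrom[k])
    outside <- setdiff(same_chrom, inside)
    out$external[k] <- sum(m$counts[inside, outside])
  }
  if (normalize) {
    if (total == 0) .stopf("cannot normalize: matrix has no intra-chromosomal counts")
    out$internal <- out$internal / total
    out$external <- out$external / total
  }
  out
}

#' Empirical-null fold-change test for TAD interactions
#'
#' Within-condition replicate log2 ratios of depth-normalized TAD counts are
#' pooled across both conditions into a background distribution (internal and
#' external handled separately). The observed statistic per replicate pairing
#' `k` is the log2 fold change condition2-rep-k over condition1-rep-k; its
#' two-sided empirical p-value is
#' `(1 + 2 * min(#background <= obs, #background >= obs)) / (N + 1)`, capped
#' at 1. A TAD is significant when every pairing's internal p-value is below
#' `alpha`. A pseudocount of 0.5 (on the common depth-equalized count scale)
#' guards the logarithm against zeros.
#'
#' @param cond1,cond2 Lists of `ContactMatrix` replicates (>= 2 each).
#' @param tads TAD interval table.
#' @param alpha Significance level per pairing (default 0.05).
#' @return `data.frame` of class `TadTest`: per-TAD normalized counts,
#'   `log2fc_internal`, `log2fc_external`, per-pairing `p_internal_k` /
#'   `p_external_k`, and `significant`.
#' @export
tad_foldchange_test <- function(cond1, cond2, tads, alpha = 0.05) {
  if (length(cond1) < 2L || length(cond2) < 2L) {
    .stopf("need at least 2 replicates per condition")
  }
  n_rep <- min(length(cond1), length(cond2))
  samples <- c(setNames(cond1, paste0("c1r", seq_along(cond1))),
               setNames(cond2, paste0("c2r", seq_along(cond2))))
  counts <- lapply(samples, function(m) tad_counts(m, tads, normalize = TRUE))
  base <- counts[[1L]][, c("tad_id", "chrom", "start", "end", "n_bins")]
  # depth-equalized count scale: normalized fractions put back on the mean
  # raw-total scale, + 0.5 pseudocount, so log2 ratios are well defined
  mean_total <- mean(vapply(samples, matrix_mass, 0, intra_only = TRUE))
  val <- function(s, what) counts[[s]][[what]] * mean_total + 0.5
  out <- base
  for (s in names(samples)) {
    out[[paste0("internal_", s)]] <- val(s, "internal")
    out[[paste0("external_", s)]] <- val(s, "external")
  }
  for (what in c("internal", "external")) {
    bg <- unlist(lapply(1:2, function(cond) {
      reps <- grep(paste0("^", what, "_c", cond), names(out), value = TRUE)
      combn(reps, 2L, function(pr) log2(out[[pr[1L]]] / out[[pr[2L]]]),
            simplify = TRUE)
    }))
    obs_fc <- matrix(0, nrow(out), n_rep)
    pmat <- matrix(1, nrow(out), n_rep)
    for (r in seq_len(n_rep)) {
      obs <- log2(out[[paste0(what, "_c2r", r)]] /
                    out[[paste0(what, "_c1r", r)]])
      obs_fc[, r] <- obs
      pmat[, r] <- vapply(obs, function(o) {
        min(1, (1 + 2 * min(sum(bg <= o), sum(bg >= o))) / (length(bg) + 1))
      }, 0)
      out[[paste0("p_", what, "_", r)]] <- pmat[, r]
    }
    out[[paste0("log2fc_", what)]] <- rowMeans(obs_fc)
    if (what == "internal") internal_p <- pmat
  }
  out$significant <- apply(internal_p < alpha, 1L, all)
  class(out) <- c("TadTest", "data.frame")
  out
}

#' Sigma-deviation categories of TAD fold changes
#'
#' TADs are grouped by how far their internal log2 fold change deviates from
#' the all-TAD mean, in standard-deviation units. The default edges
#' (-2, -1, -0.5, 0.5, 1, 2) produce seven categories, 1 = strongest
#' decrease, 7 = strongest increase.
#'
#' @param log2fc Numeric vector of per-TAD internal log2 fold changes.
#' @param edges_in_sigma Increasing z-score cut points.
#' @return Integer category per TAD, in `1..(length(edges_in_sigma) + 1)`.
#' @export
sigma_categories <- function(log2fc, edges_in_sigma = c(-2, -1, -0.5, 0.5, 1, 2)) {
  if (length(log2fc) < 2L) .stopf("need at least 2 TADs")
  s <- sd(log2fc)
  if (s == 0) .stopf("zero standard deviation of fold changes")
  z <- (log2fc - mean(log2fc)) / s
  findInterval(z, edges_in_sigma) + 1L
}

#' Distribution of DEG status across TAD categories
#'
#' Per sigma category: counts and within-category proportions of up, down and
#' stable genes, plus a `total` row over all TADs. Genes whose TSS falls
#' outside every TAD are reported in a `no_TAD` row.
#'
#' @param tad_tests A `TadTest` table with a `category` column (see
#'   [sigma_categories()]).
#' @param genes Gene table with `chrom`, `tss`, `de_status` (see
#'   [classify_degs()]).
#' @return `data.frame` with one row per category (plus `total`, `no_TAD`):
#'   counts `n_up`, `n_down`, `n_stable` and proportions `p_up`, `p_down`,
#'   `p_stable` summing to 1 where the row is non-empty.
#' @export
deg_category_distribution <- function(tad_tests, genes) {
  if (is.null(tad_tests$category)) {
    .stopf("tad_tests must carry a 'category' column")
  }
  tad_of_gene <- rep(NA_character_, nrow(genes))
  for (k in seq_len(nrow(tad_tests))) {
    hit <- genes$chrom == tad_tests$chrom[k] &
      genes$tss >= tad_tests$start[k] & genes$tss < tad_tests$end[k]
    tad_of_gene[hit] <- tad_tests$tad_id[k]
  }
  cat_of_gene <- tad_tests$category[match(tad_of_gene, tad_tests$tad_id)]
  grp <- ifelse(is.na(cat_of_gene), "no_TAD", as.character(cat_of_gene))
  levels <- c(sort(unique(tad_tests$category)), "total", "no_TAD")
  rows <- lapply(levels, function(lv) {
    sel <- if (lv == "total") !is.na(cat_of_gene) else grp == lv
    st <- table(factor(genes$de_status[sel], levels = c("up", "down", "stable")))
    n <- sum(st)
    data.frame(category = lv, n_genes = n,
               n_up = st[["up"]], n_down = st[["down"]], n_stable = st[["stable"]],
               p_up = if (n) st[["up"]] / n else NA_real_,
               p_down = if (n) st[["down"]] / n else NA_real_,
               p_stable = if (n) st[["stable"]] / n else NA_real_)
  })
  do.call(rbind, rows)
}

#' TAD boundary stability between two TAD sets
#'
#' Boundaries are the unique TAD start/end positions per chromosome. A
#' boundary of the first set is *stable* iff some boundary of the second set
#' lies within `tolerance` bp. Returns the stable fraction and the full
#' distance-to-nearest table.
#'
#' @param tads1,tads2 TAD interval tables.
#' @param tolerance Maximum distance in bp (default one 40-kb bin).
#' @return List with `fraction_stable` and `distances` (`chrom`, `boundary`,
#'   `distance`, `stable`).
#' @export
boundary_stability <- function(tads1, tads2, tolerance = 40000L) {
  if (nrow(tads1) == 0L || nrow(tads2) == 0L) .stopf("empty TAD set")
  rows <- list()
  for (ch in unique(tads1$chrom)) {
    b1 <- sort(unique(c(tads1$start[tads1$chrom == ch],
                        tads1$end[tads1$chrom == ch])))
    b2 <- sort(unique(c(tads2$start[tads2$chrom == ch],
                        tads2$end[tads2$chrom == ch])))
    d <- if (length(b2)) vapply(b1, function(x) min(abs(b2 - x)), 0) else
      rep(Inf, length(b1))
    rows[[ch]] <- data.frame(chrom = ch, boundary = b1, distance = d,
                             stable = d <= tolerance)
  }
  distances <- do.call(rbind, rows)
  rownames(distances) <- NULL
  list(fraction_stable = mean(distances$stable), distances = distances)
}
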