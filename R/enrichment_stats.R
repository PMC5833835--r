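# Downstream statistics: Fisher enrichment, Mann-Whitney comparisons, region
# signal fold changes, peak enrichment in Gain/Loss regions, network hubs.

#' Fisher exact enrichment test on a 2x2 table
#'
#' Exact hypergeometric tail probability for the stated alternative, with the
#' sample odds ratio `(a d) / (b c)` (infinite when `b c == 0` and `a d > 0`).
#' Rows are in-set / out-of-set, columns positive / negative.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise:
#'   `[[a, b], [c, d]]`).
#' @param alternative `"greater"` (default, enrichment), `"less"`, or
#'   `"two.sided"`.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(a, b, c, d, alternative = c("greater", "less",
                                                          "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    .stopf("table entries must be non-negative integers")
  }
  tab <- matrix(cells, 2L, 2L, byrow = TRUE)
  p <- fisher.test(tab, alternative = alternative)$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups: exact p-value for small tie-free
#' samples (`min(n1, n2) <= 8`), normal approximation with tie correction
#' otherwise.
#'
#' @param group1,group2 Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `U` (statistic for `group1`) and `p_value`.
#' @export
mann_whitney <- function(group1, group2,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(group1) || !length(group2)) .stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(group1, group2)) > 0L
  exact <- min(length(group1), length(group2)) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(group1, group2,
                                     alternative = alternative,
                                     exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-region log2 signal fold change
#'
#' For each region, `log2((sum of signal2 + eps) / (sum of signal1 + eps))`
#' over the bins the region covers; the pseudocount `eps` guards empty
#' regions. Signals are expected depth-normalized to equal totals.
#'
#' @param signal1,signal2 Per-bin numeric signal vectors (same length).
#' @param regions List of integer bin-index vectors, one per region.
#' @param eps Pseudocount (default 0.5).
#' @return Numeric vector of per-region log2 fold changes.
#' @export
region_signal_foldchange <- function(signal1, signal2, regions, eps = 0.5) {
  if (length(signal1) != length(signal2)) .stopf("signal vectors differ in length")
  vapply(regions, function(idx) {
    if (any(idx < 1L | idx > length(signal1))) {
      .stopf("region indexes bins outside the signal domain")
    }
    log2((sum(signal2[idx]) + eps) / (sum(signal1[idx]) + eps))
  }, 0)
}

#' DEG enrichment in Gain/Loss interaction gene sets
#'
#' Per call set: counts of up/down/stable genes, and a Fisher test of DEG
#' enrichment among involved genes against the background of all genes.
#'
#' @param gain_genes,loss_genes Character vectors of gene ids.
#' @param all_genes Gene table with `gene_id` and `de_status`.
#' @return List with `table` (per-set DEG composition) and `fisher` (per-set
#'   odds ratio and p-value of DEG enrichment, alternative "greater").
#' @export
interaction_deg_enrichment <- function(gain_genes, loss_genes, all_genes) {
  unknown <- setdiff(c(gain_genes, loss_genes), all_genes$gene_id)
  if (length(unknown)) {
    .stopf("unknown gene id(s): %s", paste(head(unknown, 5L), collapse = ", "))
  }
  is_deg <- all_genes$de_status %in% c("up", "down")
  total_deg <- sum(is_deg)
  total <- nrow(all_genes)
  one <- function(set) {
    sel <- all_genes$gene_id %in% set
    st <- table(factor(all_genes$de_status[sel],
                       levels = c("up", "down", "stable")))
    n_deg <- st[["up"]] + st[["down"]]
    fish <- fisher_enrichment(n_deg, sum(sel) - n_deg,
                              total_deg - n_deg,
                              (total - sum(sel)) - (total_deg - n_deg),
                              alternative = "greater")
    list(n = sum(sel), n_up = st[["up"]], n_down = st[["down"]],
         n_stable = st[["stable"]], odds_ratio = fish$odds_ratio,
         p_value = fish$p_value)
  }
  res <- list(Gain = one(gain_genes), Loss = one(loss_genes))
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    data.frame(set = nm, n = res[[nm]]$n, n_up = res[[nm]]$n_up,
               n_down = res[[nm]]$n_down, n_stable = res[[nm]]$n_stable)
  }))
  list(table = tab,
       fisher = data.frame(set = names(res),
                           odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
                           p_value = vapply(res, `[[`, 0, "p_value")))
}

#' Condition-specific peak enrichment in Gain vs Loss regions
#'
#' For gene regions and regulatory regions separately, builds the 2x2 table
#' (bin of a Gain pair vs bin of a Loss pair) x (contains a
#' condition-2-specific peak vs a condition-1-specific peak) and tests it
#' with [fisher_enrichment()] (alternative "greater": condition-2-specific
#' peaks concentrate in Gain regions).
#'
#' @param spec1,spec2 Condition-1- / condition-2-specific peak tables (from
#'   [overlap_partition()] of the two conditions' peaks).
#' @param annotations Bin annotations from [annotate_bins()].
#' @param calls Called pair table from [call_gain_loss()].
#' @return List per region type (`gene_region`, `regulatory_region`):
#'   the 2x2 table and the Fisher result, or `NULL` (with a warning) when a
#'   call set is empty.
#' @export
peak_region_enrichment <- function(spec1, spec2, annotations, calls) {
  bins_with_peak <- function(peaks) {
    if (!nrow(peaks)) return(integer())
    mid <- (peaks$start + peaks$end) %/% 2L
    idx <- integer()
    for (ch in unique(peaks$chrom)) {
      bsel <- which(annotations$chrom == ch)
      k <- findInterval(mid[peaks$chrom == ch], annotations$start[bsel])
      k <- k[k >= 1L & k <= length(bsel)]
      idx <- c(idx, bsel[k])
    }
    unique(idx)
  }
  has1 <- bins_with_peak(spec1)
  has2 <- bins_with_peak(spec2)
  out <- list()
  for (what in c("gene_region", "regulatory_region")) {
    bcol <- if (what == "gene_region") "gene_bin" else "reg_bin"
    gain_bins <- unique(calls[[bcol]][calls$call == "Gain"])
    loss_bins <- unique(calls[[bcol]][calls$call == "Loss"])
    if (!length(gain_bins) || !length(loss_bins)) {
      .warnf("empty Gain or Loss call set; %s table omitted", what)
      out[[what]] <- NULL
      next
    }
    a <- sum(gain_bins %in% has2); b <- sum(gain_bins %in% has1)
    c_ <- sum(loss_bins %in% has2); d <- sum(loss_bins %in% has1)
    fish <- fisher_enrichment(a, b, c_, d, alternative = "greater")
    out[[what]] <- list(table = matrix(c(a, b, c_, d), 2L, 2L, byrow = TRUE,
                                       dimnames = list(c("Gain", "Loss"),
                                                       c("cond2_specific",
                                                         "cond1_specific"))),
                        odds_ratio = fish$odds_ratio,
                        p_value = fish$p_value)
  }
  out
}

#' Hub degrees in an induced regulatory subnetwork
#'
#' Collapses duplicate directed edges, induces the subnetwork on
#' `focus_nodes` (both endpoints in the set), and returns total degree
#' (in + out) per focus node, sorted by degree (stable ties by id).
#'
#' @param edges `data.frame` with columns `source` and `target`.
#' @param focus_nodes Character vector of node ids.
#' @return `data.frame` (`node`, `degree`) sorted descending.
#' @export
network_hub_degrees <- function(edges, focus_nodes) {
  edges <- unique(edges[, c("source", "target")])
  sub <- edges[edges$source %in% focus_nodes & edges$target %in% focus_nodes, ]
  if (!nrow(sub)) .warnf("induced subnetwork has no edges")
  deg <- setNames(numeric(length(focus_nodes)), focus_nodes)
  tb <- table(c(sub$source, sub$target))
  deg[names(tb)] <- as.numeric(tb)
  out <- data.frame(node = names(deg), degree = as.numeric(deg))
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  out
}
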