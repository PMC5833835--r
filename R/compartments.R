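# A/B compartment assignment from the first principal component of the
# O/E correlation matrix, and replicate-consistent compartment-switch calls.

#' First-principal-component compartment track (unoriented)
#'
#' Per chromosome: observed/expected transform of the balanced matrix,
#' Pearson correlation matrix across bin contact profiles, then the first
#' principal component of that correlation matrix. The eigenvector sign is
#' arbitrary at this stage; see [orient_and_label()]. Masked bins get
#' `pc1 = 0` and label `undefined`.
#'
#' @param m A balanced `ContactMatrix` (run [ice_balance()] first).
#' @return `data.frame` (`chrom`, `start`, `end`, `index`, `pc1`, `label`)
#'   of class `CompartmentTrack`; labels are `A` (`pc1 > 0`), `B`
#'   (`pc1 < 0`), `undefined` (`pc1 == 0`).
#' @export
pc1_track <- function(m) {
  oe <- oe_transform(m)
  track <- m$bins
  track$pc1 <- 0
  for (ch in unique(m$bins$chrom)) {
    idx <- m$bins$index[m$bins$chrom == ch]
    ok <- idx[!is.na(m$weights[idx])]
    if (length(ok) < 10L) .stopf("fewer than 10 unmasked bins on %s", ch)
    sub <- oe[ok, ok, drop = FALSE]
    sub[!is.finite(sub)] <- 0
    sds <- apply(sub, 2L, sd)
    if (all(sds == 0)) next  # no structure: leave pc1 at 0
    cm <- suppressWarnings(cor(sub))
    cm[!is.finite(cm)] <- 0
    if (all(cm == 0)) .stopf("degenerate (rank-0) matrix on %s", ch)
    pc <- prcomp(cm, center = TRUE, scale. = FALSE)
    track$pc1[ok] <- pc$x[, 1L]
  }
  track$label <- ifelse(track$pc1 > 0, "A",
                        ifelse(track$pc1 < 0, "B", "undefined"))
  class(track) <- c("CompartmentTrack", "data.frame")
  track
}

#' Orient PC1 and assign A/B labels
#'
#' The sign of an eigenvector is arbitrary, so the track is oriented per
#' chromosome against a marker of activity: the sign is flipped wherever the
#' correlation between `pc1` and the marker density (e.g. TSS count or
#' active-mark peak count per bin) is negative, making A the active
#' compartment by construction.
#'
#' @param track A `CompartmentTrack` from [pc1_track()].
#' @param marker_density Numeric vector, one non-negative value per bin.
#' @return The oriented track with final `A`/`B`/`undefined` labels.
#' @export
orient_and_label <- function(track, marker_density) {
  if (length(marker_density) != nrow(track)) {
    .stopf("marker_density must have one value per bin")
  }
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    md <- marker_density[sel]
    if (sd(md) == 0) .stopf("marker density has zero variance on %s", ch)
    if (sd(track$pc1[sel]) == 0) next
    if (cor(track$pc1[sel], md) < 0) track$pc1[sel] <- -track$pc1[sel]
  }
  track$label <- ifelse(track$pc1 > 0, "A",
                        ifelse(track$pc1 < 0, "B", "undefined"))
  track
}

#' TSS density per bin
#'
#' Convenience marker for [orient_and_label()]: number of TSS per bin.
#'
#' @param bins Bin table.
#' @param genes Gene table with `chrom` and `tss`.
#' @return Integer vector, one count per bin.
#' @export
tss_density <- function(bins, genes) {
  out <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    sel <- which(bins$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    if (!length(tss)) next
    counts <- table(findInterval(tss, bins$start[sel]))
    keep <- as.integer(names(counts))
    valid <- keep >= 1L & keep <= length(sel)
    out[sel[keep[valid]]] <- as.integer(counts[valid])
  }
  out
}

#' Replicate-consistent compartment changes between conditions
#'
#' A bin switches A to B only when *every* condition-1 replicate labels it A
#' and *every* condition-2 replicate labels it B (B to A symmetric); a bin
#' any replicate leaves undefined is undefined; anything else is unchanged.
#' Requiring agreement across replicates is what keeps the switch calls
#' conservative.
#'
#' @param cond1_tracks,cond2_tracks Lists of oriented `CompartmentTrack`s
#'   (one per replicate), all on identical bins.
#' @return List with `changes` (per-bin `data.frame` with a `change` column)
#'   and `summary` (fraction of bins per category; sums to 1).
#' @export
compartment_changes <- function(cond1_tracks, cond2_tracks) {
  all_tracks <- c(cond1_tracks, cond2_tracks)
  base <- all_tracks[[1L]][, c("chrom", "start", "end", "index")]
  for (t in all_tracks) {
    if (!identical(t[, c("chrom", "start", "end", "index")], base)) {
      .stopf("tracks are on different bin tables")
    }
  }
  lab <- function(tracks) do.call(cbind, lapply(tracks, `[[`, "label"))
  l1 <- lab(cond1_tracks)
  l2 <- lab(cond2_tracks)
  undef <- apply(l1 == "undefined", 1L, any) | apply(l2 == "undefined", 1L, any)
  all1A <- apply(l1 == "A", 1L, all); all1B <- apply(l1 == "B", 1L, all)
  all2A <- apply(l2 == "A", 1L, all); all2B <- apply(l2 == "B", 1L, all)
  change <- rep("unchanged", nrow(base))
  change[all1A & all2B] <- "A_to_B"
  change[all1B & all2A] <- "B_to_A"
  change[undef] <- "undefined"
  out <- base
  out$change <- factor(change,
                       levels = c("unchanged", "A_to_B", "B_to_A", "undefined"))
  summary <- table(out$change) / nrow(out)
  list(changes = out, summary = as.numeric(summary) |>
         setNames(names(summary)))
}
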