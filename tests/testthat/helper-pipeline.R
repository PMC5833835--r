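# Shared pipeline drivers for tests that exercise several modules together.

# a fast one-chromosome configuration for module-level tests
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 8e6,
               depth = 2e5, n_planted_gain = 8L, n_planted_loss = 8L,
               n_genes = 80L)
  over <- list(...)
  args[names(over)] <- over
  do.call(truth_config, args)
}

# replicate-intersected ("convincing") peaks of one mark and condition
convincing_peaks <- function(pe, mark, cond) {
  op <- overlap_partition(pe$peaks[[mark]][[cond]]$rep1,
                          pe$peaks[[mark]][[cond]]$rep2)
  op$common_a
}

# full differential gene-regulatory interaction pipeline on simulated data;
# returns the called pair table plus the planted truth keys
run_gain_loss_pipeline <- function(cfg) {
  tr <- generate_truth(cfg)
  maps <- simulate_contact_maps(tr, cfg)
  pe <- simulate_peaks_expression(tr, cfg)
  prom <- rbind(convincing_peaks(pe, "promoter", "cond1"),
                convincing_peaks(pe, "promoter", "cond2"))
  dist <- rbind(convincing_peaks(pe, "distal", "cond1"),
                convincing_peaks(pe, "distal", "cond2"))
  genes <- classify_degs(pe$expression)
  ann <- annotate_bins(tr$bins, prom, dist, genes, tr$tads)
  cand <- extract_candidate_pairs(ann, maps$cond1, maps$cond2)
  mars <- mars_test(cand$C1, cand$C2, attr(cand, "n1"), attr(cand, "n2"))
  calls <- call_gain_loss(cbind(cand, mars[, c("M", "A", "p1_hat", "p2_hat", "z", "p")]))
  list(truth = tr, maps = maps, peaks_expr = pe, annotations = ann,
       calls = calls)
}

gain_loss_scores <- function(pip) {
  calls <- pip$calls
  planted <- pip$truth$planted_pairs
  key <- paste(calls$gene_bin, calls$reg_bin)
  tkey <- paste(planted$gene_bin, planted$reg_bin)
  tdir <- setNames(planted$direction, tkey)
  called <- calls$call != "NS"
  tp <- sum(called & key %in% tkey & as.character(calls$call) == tdir[key])
  fp <- sum(called) - tp
  fn <- nrow(planted) - tp
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       n_called = sum(called))
}

# per-replicate oriented compartment tracks for all four samples
call_compartment_tracks <- function(tr, maps) {
  md <- tss_density(tr$bins, tr$genes)
  out <- list(cond1 = list(), cond2 = list())
  for (cond in 1:2) {
    for (r in 1:2) {
      m <- ice_balance(maps[[paste0("cond", cond)]][[paste0("rep", r)]])
      out[[paste0("cond", cond)]][[paste0("rep", r)]] <-
        orient_and_label(pc1_track(m), md)
    }
  }
  out
}
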