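# Synthetic toy system with planted ground truth: genome, TADs, compartments,
# contact maps (2 conditions x 2 replicates), peaks, expression, and
# linker-bearing read pairs. Every downstream stage of the pipeline is
# testable against the planted truth without any external data.

#' Configuration of the synthetic truth
#'
#' Bundles and validates every knob of the generator. The defaults define a
#' toy two-chromosome genome whose scale mirrors the study design: 40-kb
#' analysis bins, TADs averaging ~400 kb, two replicates per condition, and a
#' per-replicate depth obtained by scaling the study's interaction count to
#' the toy genome size.
#'
#' @param seed Integer seed; all generator stages derive their randomness
#'   from it.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (must be a multiple of
#'   `bin_size`).
#' @param bin_size Analysis bin width in bp (default 40,000).
#' @param tad_size_range Length-2 vector, min/max TAD size in bp; rounded to
#'   whole bins, at least 2 bins.
#' @param compartment_size_range Length-2 vector, min/max size in bp of the
#'   alternating A/B compartment blocks.
#' @param decay_exponent Power-law exponent `alpha` of the contact distance
#'   decay (expected counts proportional to `(d+1)^-alpha` in bin units).
#' @param tad_block Structural within-TAD contact enrichment applied to every
#'   TAD in both conditions (> 1 produces the familiar diagonal blocks).
#' @param tad_boost Condition-2 internal contact multiplier `beta` applied to
#'   the randomly chosen "boosted" TADs.
#' @param compartment_affinity Multiplier `gamma` for bin pairs in the same
#'   compartment.
#' @param planted_effect Contact fold change `delta` of planted Gain pairs in
#'   condition 2 (`1/delta` for Loss pairs).
#' @param depth Expected total contact count per replicate.
#' @param inter_frac Fraction of the depth placed as a flat inter-chromosomal
#'   floor.
#' @param n_planted_gain,n_planted_loss Numbers of planted Gain / Loss
#'   gene-regulatory pairs.
#' @param planted_distance_range Length-2 integer vector, min/max separation
#'   in bins between a planted pair's gene bin and regulatory bin (default
#'   1-4 bins, i.e. 40-160 kb at the default bin size, the distance scale of
#'   the promoter-enhancer loops the pipeline targets).
#' @param frac_boosted_tads Fraction of TADs given the condition-2 internal
#'   boost.
#' @param frac_ab_flip Fraction of bins whose compartment label flips A to B
#'   in condition 2, planted as boundary shifts of existing B blocks
#'   (default 0; the compartment-switch study scenario plants 1%).
#' @param n_genes Total number of genes.
#' @param frac_expressed Fraction of background genes flagged expressed.
#' @param prob_gene_in_A Probability that a background gene lands in an
#'   A-compartment bin (drives the marker density used to orient PC1).
#' @param planted_lfc Mean absolute log2 expression fold change of genes
#'   attached to planted pairs.
#' @param expr_noise_sd Per-replicate expression noise s.d. (log2 scale).
#' @param n_expr_reps Simulated expression replicates per condition.
#' @param tad_de_coupling Mean log2 expression fold change added to genes
#'   living in boosted TADs (emulates the coupling between increased TAD
#'   internal interactions and upregulation).
#' @param coupling_prob Probability that a planted Gain (Loss) regulatory bin
#'   carries a condition-2-specific (condition-1-specific) distal peak rather
#'   than a shared one.
#' @param promoter_window Half-width in bp of the promoter window around each
#'   TSS.
#' @return A validated list of class `TruthConfig`.
#' @export
truth_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 2e7,
                         bin_size = 4e4,
                         tad_size_range = c(280e3, 520e3),
                         compartment_size_range = c(1e6, 3e6),
                         decay_exponent = 1.0,
                         tad_block = 2.0,
                         tad_boost = 2.0,
                         compartment_affinity = 2.0,
                         planted_effect = 2.0,
                         depth = 1e6,
                         inter_frac = 0.05,
                         n_planted_gain = 30L,
                         n_planted_loss = 30L,
                         planted_distance_range = c(1L, 4L),
                         frac_boosted_tads = 0,
                         frac_ab_flip = 0,
                         n_genes = 400L,
                         frac_expressed = 0.85,
                         prob_gene_in_A = 0.85,
                         planted_lfc = 2.0,
                         expr_noise_sd = 0.3,
                         n_expr_reps = 2L,
                         tad_de_coupling = 1.0,
                         coupling_prob = 1.0,
                         promoter_window = 2000L) {
  cfg <- as.list(environment())
  if (cfg$chrom_length %% cfg$bin_size != 0) {
    .stopf("bin_size must divide chrom_length")
  }
  if (any(c(cfg$decay_exponent, cfg$tad_block, cfg$tad_boost,
            cfg$compartment_affinity, cfg$planted_effect) <= 0)) {
    .stopf("all contact multipliers and the decay exponent must be positive")
  }
  if (cfg$tad_size_range[1] < 2 * cfg$bin_size) {
    .stopf("TADs must span at least 2 bins")
  }
  if (cfg$frac_boosted_tads < 0 || cfg$frac_boosted_tads > 1 ||
      cfg$frac_ab_flip < 0 || cfg$frac_ab_flip > 1 ||
      cfg$coupling_prob < 0 || cfg$coupling_prob > 1) {
    .stopf("fractions and probabilities must lie in [0, 1]")
  }
  if (cfg$depth < 0) .stopf("depth must be non-negative")
  if (cfg$planted_distance_range[1] < 1L) {
    .stopf("planted pairs need distinct bins (distance >= 1)")
  }
  class(cfg) <- "TruthConfig"
  cfg
}

#' Generate the planted ground truth
#'
#' Lays out TADs (tiling each chromosome without overlap), alternating A/B
#' compartment blocks with a condition-2 A-to-B flip set, boosted-TAD labels,
#' genes (with the planted differential-expression assignments attached to
#' planted pairs), regulatory bins, and the planted Gain/Loss gene-regulatory
#' bin pairs, all within-TAD by construction. Deterministic given
#' `config$seed`.
#'
#' @param config A `TruthConfig` from [truth_config()].
#' @return A list of class `TruthTables` with components `chrom_sizes`,
#'   `bins`, `tads`, `compartments`, `genes`, `reg_bins`, `planted_pairs`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "TruthConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  bins <- bin_table(chrom_sizes, config$bin_size)
  nb <- config$chrom_length %/% config$bin_size

  tad_bins <- round(config$tad_size_range / config$bin_size)
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    sizes <- integer()
    pos <- 0L
    while (pos < nb) {
      s <- .sample1(seq(tad_bins[1], tad_bins[2]))
      s <- min(s, nb - pos)
      sizes <- c(sizes, s)
      pos <- pos + s
    }
    ends <- cumsum(sizes)
    data.frame(chrom = ch,
               start = c(0L, head(ends, -1L)) * config$bin_size,
               end = ends * config$bin_size)
  }))
  # merge a trailing fragment smaller than 2 bins into its neighbour
  short <- (tads$end - tads$start) < 2L * config$bin_size
  if (any(short)) {
    for (k in which(short)) tads$end[k - 1L] <- tads$end[k]
    tads <- tads[!short, ]
  }
  tads$tad_id <- paste0("tad_", seq_len(nrow(tads)))
  n_boost <- round(config$frac_boosted_tads * nrow(tads))
  tads$boosted <- FALSE
  if (n_boost > 0) tads$boosted[sample(nrow(tads), n_boost)] <- TRUE

  comp_bins <- round(config$compartment_size_range / config$bin_size)
  label1 <- unlist(lapply(chroms, function(ch) {
    lab <- character()
    cur <- sample(c("A", "B"), 1L)
    while (length(lab) < nb) {
      lab <- c(lab, rep(cur, .sample1(seq(comp_bins[1], comp_bins[2]))))
      cur <- if (cur == "A") "B" else "A"
    }
    lab[seq_len(nb)]
  }))
  # condition-2 A-to-B switches are planted as compartment-boundary shifts:
  # contiguous A runs adjacent to a B block flip, extending that block. This
  # is the form real compartment changes take (whole regions, not isolated
  # bins), and it keeps flipped bins at a normal B-bin coverage profile.
  label2 <- label1
  n_flip <- round(config$frac_ab_flip * nrow(bins))
  flipped <- integer()
  if (n_flip > 0) {
    chrom_of_bin <- bins$chrom
    cand <- which(label1 == "A" & c(label1[-1L], "x") == "B" &
                    chrom_of_bin == c(chrom_of_bin[-1L], ""))
    cand <- c(cand, -which(label1 == "A" & c("x", label1[-nrow(bins)]) == "B" &
                             chrom_of_bin == c("", chrom_of_bin[-nrow(bins)])))
    if (!length(cand)) .stopf("no A/B boundaries available to plant flips")
    cand <- sample(cand)
    remaining <- n_flip
    ci <- 1L
    while (remaining > 0L) {
      if (ci > length(cand)) .stopf("not enough A/B boundaries to plant %d flipped bins", n_flip)
      edge <- cand[ci]; ci <- ci + 1L
      run_len <- min(remaining, .sample1(2:4))
      step <- if (edge > 0) -1L else 1L   # extend the B block into the A run
      b <- abs(edge)
      run <- integer()
      while (length(run) < run_len && b >= 1L && b <= nrow(bins) &&
             label2[b] == "A" && chrom_of_bin[b] == chrom_of_bin[abs(edge)]) {
        run <- c(run, b)
        b <- b + step
      }
      label2[run] <- "B"
      flipped <- c(flipped, run)
      remaining <- remaining - length(run)
    }
    flipped <- sort(flipped)
  }
  compartments <- data.frame(bins,
                             label_cond1 = label1, label_cond2 = label2,
                             flipped = seq_len(nrow(bins)) %in% flipped)

  tad_of_bin <- .assign_bins_to_tads(bins, tads)

  # planted gene-regulatory pairs: gene bin and regulatory bin in one TAD,
  # 2-6 bins apart; one dedicated gene per pair
  n_plant <- config$n_planted_gain + config$n_planted_loss
  min_tad_bins <- config$planted_distance_range[1] + 2L
  eligible <- which((tads$end - tads$start) %/% config$bin_size >= min_tad_bins)
  if (length(eligible) == 0L && n_plant > 0) {
    .stopf("no TAD is large enough (>= %d bins) to hold a planted pair", min_tad_bins)
  }
  planted <- list()
  used_cells <- character()
  used_bins <- integer()
  dirs <- c(rep("Gain", config$n_planted_gain),
            rep("Loss", config$n_planted_loss))
  attempts <- 0L
  for (dr in dirs) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 200L * max(1L, n_plant)) {
        .stopf("could not place %d planted pairs in %d eligible TADs; reduce n_planted_gain/n_planted_loss",
               n_plant, length(eligible))
      }
      tk <- .sample1(eligible)
      tb <- which(tad_of_bin == tads$tad_id[tk])
      dmin <- config$planted_distance_range[1]
      dmax <- config$planted_distance_range[2]
      gi <- .sample1(tb[seq_len(max(1L, length(tb) - dmin))])
      jmax <- min(max(tb), gi + dmax)
      if (jmax < gi + dmin) next
      rj <- .sample1(seq(gi + dmin, jmax))
      cell <- paste(gi, rj)
      if (cell %in% used_cells || rj %in% used_bins || gi %in% used_bins) next
      used_cells <- c(used_cells, cell)
      used_bins <- c(used_bins, gi, rj)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_bin = gi, reg_bin = rj, tad_id = tads$tad_id[tk],
        chrom = bins$chrom[gi], direction = dr)
      break
    }
  }
  planted_pairs <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_bin = integer(), reg_bin = integer(),
               tad_id = character(), chrom = character(),
               direction = character())

  # genes: one per planted pair (in its gene bin), plus background genes
  # preferentially in A bins (the orientation marker for compartment calling)
  gene_rows <- list()
  if (nrow(planted_pairs)) {
    for (k in seq_len(nrow(planted_pairs))) {
      gene_rows[[k]] <- .place_gene(bins, planted_pairs$gene_bin[k], config,
                                    planted = planted_pairs$direction[k])
    }
  }
  n_bg <- max(0L, config$n_genes - length(gene_rows))
  reg_taken <- planted_pairs$reg_bin
  a_bins <- setdiff(which(label1 == "A"), reg_taken)
  b_bins <- setdiff(which(label1 == "B"), reg_taken)
  for (k in seq_len(n_bg)) {
    pool <- if (runif(1) < config$prob_gene_in_A && length(a_bins)) a_bins else b_bins
    gene_rows[[length(gene_rows) + 1L]] <-
      .place_gene(bins, .sample1(pool), config, planted = "none")
  }
  genes <- do.call(rbind, gene_rows)
  genes$gene_id <- paste0("g", seq_len(nrow(genes)))
  genes$tad_id <- tad_of_bin[genes$bin]
  bg <- genes$planted == "none"
  genes$expressed <- TRUE
  genes$expressed[bg] <- runif(sum(bg)) < config$frac_expressed
  planted_pairs$gene_id <- genes$gene_id[match(planted_pairs$gene_bin, genes$bin)]

  # background regulatory bins: one gene-free bin per sufficiently large TAD
  gene_bins <- unique(genes$bin)
  reg_extra <- integer()
  for (tk in seq_len(nrow(tads))) {
    tb <- which(tad_of_bin == tads$tad_id[tk])
    free <- setdiff(tb, c(gene_bins, planted_pairs$reg_bin))
    if (length(free) >= 1L) reg_extra <- c(reg_extra, .sample1(free))
  }
  reg_bins <- data.frame(
    bin = c(planted_pairs$reg_bin, reg_extra),
    tad_id = tad_of_bin[c(planted_pairs$reg_bin, reg_extra)],
    planted = c(planted_pairs$direction, rep("none", length(reg_extra))))
  reg_bins <- reg_bins[!duplicated(reg_bins$bin), ]

  structure(list(chrom_sizes = chrom_sizes, bins = bins, tads = tads,
                 compartments = compartments, genes = genes,
                 reg_bins = reg_bins, planted_pairs = planted_pairs,
                 config = config),
            class = "TruthTables")
}

.place_gene <- function(bins, bin_idx, config, planted) {
  off <- .sample1(seq(config$promoter_window,
                      config$bin_size - config$promoter_window))
  data.frame(chrom = bins$chrom[bin_idx],
             tss = bins$start[bin_idx] + off,
             strand = sample(c("+", "-"), 1L),
             bin = bin_idx, planted = planted)
}

# tad id per bin by the bin-midpoint rule; NA outside every TAD
.assign_bins_to_tads <- function(bins, tads) {
  mid <- (bins$start + bins$end) %/% 2L
  out <- rep(NA_character_, nrow(bins))
  for (k in seq_len(nrow(tads))) {
    hit <- bins$chrom == tads$chrom[k] & mid >= tads$start[k] & mid < tads$end[k]
    out[hit] <- tads$tad_id[k]
  }
  out
}

# Expected (Poisson mean) contact matrix for one condition, unscaled.
.expected_matrix <- function(truth, config, condition) {
  bins <- truth$bins
  n <- nrow(bins)
  E <- matrix(0, n, n)
  tad_of_bin <- .assign_bins_to_tads(bins, truth$tads)
  lab <- if (condition == 1) truth$compartments$label_cond1 else
    truth$compartments$label_cond2
  boosted_ids <- truth$tads$tad_id[truth$tads$boosted]
  for (ch in unique(bins$chrom)) {
    idx <- bins$index[bins$chrom == ch]
    k <- length(idx)
    d <- abs(outer(seq_len(k), seq_len(k), "-"))
    B <- (d + 1)^(-config$decay_exponent)
    tid <- tad_of_bin[idx]
    same_tad <- !is.na(outer(tid, tid, "==")) & outer(tid, tid, "==")
    B <- B * ifelse(same_tad, config$tad_block, 1)
    same_comp <- outer(lab[idx], lab[idx], "==")
    B <- B * ifelse(same_comp, config$compartment_affinity, 1)
    if (condition == 2 && length(boosted_ids)) {
      bt <- tid %in% boosted_ids
      B <- B * ifelse(outer(bt, bt, "&") & same_tad, config$tad_boost, 1)
    }
    E[idx, idx] <- B
  }
  if (condition == 2 && nrow(truth$planted_pairs)) {
    for (k in seq_len(nrow(truth$planted_pairs))) {
      i <- truth$planted_pairs$gene_bin[k]
      j <- truth$planted_pairs$reg_bin[k]
      f <- if (truth$planted_pairs$direction[k] == "Gain")
        config$planted_effect else 1 / config$planted_effect
      E[i, j] <- E[i, j] * f
      E[j, i] <- E[j, i] * f
    }
  }
  # scale intra part to (1 - inter_frac) * depth, then add the flat
  # inter-chromosomal floor carrying inter_frac * depth
  ut <- upper.tri(E, diag = TRUE)
  intra_mass <- sum(E[ut])
  if (intra_mass > 0 && config$depth > 0) {
    E <- E * (config$depth * (1 - config$inter_frac) / intra_mass)
    inter <- outer(bins$chrom, bins$chrom, "!=")
    n_inter_ut <- sum(inter & ut)
    if (n_inter_ut > 0 && config$inter_frac > 0) {
      E[inter] <- config$depth * config$inter_frac / n_inter_ut
    }
  } else {
    E[] <- 0
  }
  E
}

#' Simulate replicate contact maps for both conditions
#'
#' Expected counts follow a distance-decay power law modulated by TAD blocks,
#' compartment affinity, the condition-2 boosted-TAD multiplier, and the
#' planted Gain/Loss pair effects; each replicate draws its upper-triangle
#' counts independently from a Poisson law around the shared expectation.
#' A flat inter-chromosomal floor carries `inter_frac` of the depth.
#'
#' @param truth `TruthTables` from [generate_truth()].
#' @param config The matching `TruthConfig`.
#' @param n_replicates Replicates per condition (default 2).
#' @return Nested list `cond1`/`cond2`, each a list of `ContactMatrix`
#'   replicates (`rep1`, `rep2`, ...).
#' @export
simulate_contact_maps <- function(truth, config, n_replicates = 2L) {
  stopifnot(inherits(truth, "TruthTables"))
  set.seed(config$seed + 1L)
  out <- list()
  for (cond in 1:2) {
    E <- .expected_matrix(truth, config, cond)
    ut <- upper.tri(E, diag = TRUE)
    reps <- list()
    for (r in seq_len(n_replicates)) {
      counts <- matrix(0, nrow(E), ncol(E))
      counts[ut] <- rpois(sum(ut), E[ut])
      counts <- counts + t(counts) - diag(diag(counts))
      reps[[paste0("rep", r)]] <- contact_matrix(
        counts, truth$bins, config$bin_size,
        metadata = list(condition = cond, replicate = r))
    }
    out[[paste0("cond", cond)]] <- reps
  }
  out
}

#' Simulate peak calls and an expression table
#'
#' Promoter-mark peaks are placed at the TSS of every expressed gene (both
#' conditions, each replicate with positional jitter); distal-mark peaks at
#' every regulatory bin. Planted Gain regulatory bins carry a
#' condition-2-specific distal peak (Loss: condition-1-specific) with
#' probability `coupling_prob`, otherwise a shared one. Observed expression
#' log2 fold changes are the planted values plus replicate-averaged noise;
#' p-values come from the generator's known-variance z-test and are BH
#' adjusted, so DEG labels can be re-derived with [classify_degs()].
#'
#' @param truth `TruthTables` from [generate_truth()].
#' @param config The matching `TruthConfig`.
#' @return List with `peaks` (nested: mark / condition / replicate peak
#'   tables) and `expression` (gene table with `log2fc` and `padj`).
#' @export
simulate_peaks_expression <- function(truth, config) {
  stopifnot(inherits(truth, "TruthTables"))
  set.seed(config$seed + 2L)
  genes <- truth$genes
  bins <- truth$bins

  promoter <- list()
  for (cond in 1:2) {
    for (r in 1:2) {
      exg <- genes[genes$expressed, ]
      jit <- sample(-200:200, nrow(exg), replace = TRUE)
      promoter[[paste0("cond", cond)]][[paste0("rep", r)]] <- data.frame(
        chrom = exg$chrom,
        start = pmax(0L, exg$tss - 1000L + jit),
        end = exg$tss + 1000L + jit,
        name = paste0("k4_", exg$gene_id, "_c", cond, "r", r),
        signal = round(exp(rnorm(nrow(exg), 2, 0.5)), 3))
    }
  }

  rb <- truth$reg_bins
  specific <- ifelse(rb$planted == "none", "both",
                     ifelse(runif(nrow(rb)) < config$coupling_prob,
                            ifelse(rb$planted == "Gain", "cond2", "cond1"),
                            "both"))
  distal <- list()
  for (cond in 1:2) {
    keep <- specific == "both" | specific == paste0("cond", cond)
    for (r in 1:2) {
      sel <- rb[keep, , drop = FALSE]
      mid <- (bins$start[sel$bin] + bins$end[sel$bin]) %/% 2L
      jit <- sample(-500:500, nrow(sel), replace = TRUE)
      distal[[paste0("cond", cond)]][[paste0("rep", r)]] <- data.frame(
        chrom = bins$chrom[sel$bin],
        start = mid - 750L + jit,
        end = mid + 750L + jit,
        name = paste0("k27_bin", sel$bin, "_c", cond, "r", r),
        signal = round(exp(rnorm(nrow(sel), 2, 0.5)), 3))
    }
  }

  true_lfc <- ifelse(genes$planted == "Gain", config$planted_lfc,
                     ifelse(genes$planted == "Loss", -config$planted_lfc, 0))
  in_boosted <- genes$tad_id %in% truth$tads$tad_id[truth$tads$boosted]
  true_lfc[in_boosted & genes$planted == "none"] <-
    true_lfc[in_boosted & genes$planted == "none"] + config$tad_de_coupling
  nr <- config$n_expr_reps
  rep_noise <- matrix(rnorm(nrow(genes) * 2L * nr, 0, config$expr_noise_sd),
                      nrow(genes))
  obs_lfc <- true_lfc +
    rowMeans(rep_noise[, seq_len(nr), drop = FALSE]) -
    rowMeans(rep_noise[, nr + seq_len(nr), drop = FALSE])
  se <- config$expr_noise_sd * sqrt(2 / nr)
  pval <- 2 * pnorm(-abs(obs_lfc) / se)
  expression <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                           tss = genes$tss, strand = genes$strand,
                           expressed = genes$expressed,
                           log2fc = obs_lfc, padj = bh_adjust(pval))

  list(peaks = list(promoter = promoter, distal = distal),
       expression = expression,
       specific = data.frame(bin = rb$bin, specific = specific))
}

#' Simulate bridge-linker read pairs with known classes
#'
#' Draws aligned pair records of the four ligation classes (full segment,
#' self-ligation, intra- and inter-chromosomal) with the strand/span geometry
#' that defines them, and composes the corresponding FASTQ reads: a 5'
#' genomic fragment, the bridge linker (forward or reverse orientation,
#' present with probability `linker_prob`), and 3' filler.
#'
#' @param truth `TruthTables` from [generate_truth()].
#' @param config The matching `TruthConfig`.
#' @param n_pairs Number of read pairs (> 0).
#' @param class_probs Named sampling probabilities of the four classes.
#' @param linker_prob Probability that a read carries the linker.
#' @param span_threshold Span (bp) separating short-range artifact geometry
#'   from genuine intra-chromosomal ligations (default 3000, the expected
#'   threshold for a 4-cutter library).
#' @param read_length Read length in bases.
#' @param linker Linker configuration from [linker_config()].
#' @param fastq_prefix If non-`NULL`, write `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (gzipped if the prefix ends in `.gz`).
#' @return List with `pairs` (aligned-pair table with `true_class`),
#'   `reads1`, `reads2` (FASTQ records as character vectors), and the file
#'   paths when written.
#' @export
simulate_read_pairs <- function(truth, config, n_pairs,
                                class_probs = c(full_segment = 0.1,
                                                self_ligation = 0.1,
                                                intra = 0.7, inter = 0.1),
                                linker_prob = 1.0,
                                span_threshold = 3000L,
                                read_length = 100L,
                                linker = linker_config(),
                                fastq_prefix = NULL) {
  stopifnot(inherits(truth, "TruthTables"))
  if (n_pairs <= 0) .stopf("n_pairs must be positive")
  set.seed(config$seed + 3L)
  chroms <- names(truth$chrom_sizes)
  len <- truth$chrom_sizes[[1L]]
  cls <- sample(names(class_probs), n_pairs, replace = TRUE,
                prob = class_probs)
  chrom1 <- sample(chroms, n_pairs, replace = TRUE)
  chrom2 <- chrom1
  inter <- cls == "inter"
  if (length(chroms) > 1L) {
    chrom2[inter] <- vapply(chrom1[inter], function(ch)
      .sample1(setdiff(chroms, ch)), "")
  } else if (any(inter)) {
    .stopf("cannot simulate inter-chromosomal pairs with a single chromosome")
  }
  span <- integer(n_pairs)
  short <- cls %in% c("full_segment", "self_ligation")
  span[short] <- sample(seq(100L, span_threshold - 100L), sum(short),
                        replace = TRUE)
  long <- cls == "intra"
  # log-uniform spans at or above the threshold
  span[long] <- round(exp(runif(sum(long), log(span_threshold),
                                log(len / 4))))
  pos1 <- integer(n_pairs)
  pos2 <- integer(n_pairs)
  strand1 <- character(n_pairs)
  strand2 <- character(n_pairs)
  same <- !inter
  pos1[same] <- sample.int(len - max(span) - 1L, sum(same), replace = TRUE)
  pos2[same] <- pos1[same] + span[same]
  pos1[inter] <- sample.int(len - 1L, sum(inter), replace = TRUE)
  pos2[inter] <- sample.int(len - 1L, sum(inter), replace = TRUE)
  # geometry: full segment = inward (+/-), self-ligation = outward (-/+),
  # long intra and inter = random strands
  fs <- cls == "full_segment"; sl <- cls == "self_ligation"
  strand1[fs] <- "+"; strand2[fs] <- "-"
  strand1[sl] <- "-"; strand2[sl] <- "+"
  rnd <- long | inter
  strand1[rnd] <- sample(c("+", "-"), sum(rnd), replace = TRUE)
  strand2[rnd] <- sample(c("+", "-"), sum(rnd), replace = TRUE)
  pairs <- data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                      chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
                      true_class = cls)

  mk_read <- function(n) {
    has_linker <- runif(n) < linker_prob
    lk <- ifelse(runif(n) < 0.5, linker$forward, linker$reverse)
    f5 <- .random_dna(n, sample(20:40, n, replace = TRUE))
    out <- character(n)
    for (k in seq_len(n)) {
      if (has_linker[k]) {
        body <- paste0(f5[k], lk[k])
        fill <- read_length - nchar(body)
        out[k] <- if (fill > 0) paste0(body, .random_dna(1L, fill)) else
          substr(body, 1L, read_length)
      } else {
        out[k] <- .random_dna(1L, read_length)
      }
    }
    list(seq = out, has_linker = has_linker)
  }
  r1 <- mk_read(n_pairs)
  r2 <- mk_read(n_pairs)
  qual <- strrep("I", read_length)
  fq <- function(rr, mate) {
    as.vector(rbind(paste0("@pair", seq_len(n_pairs), "/", mate),
                    rr$seq, "+", substr(qual, 1L, nchar(rr$seq))))
  }
  reads1 <- fq(r1, 1L)
  reads2 <- fq(r2, 2L)
  paths <- NULL
  if (!is.null(fastq_prefix)) {
    gz <- grepl("\\.gz$", fastq_prefix)
    base <- sub("\\.gz$", "", fastq_prefix)
    p1 <- paste0(base, "_1.fastq", if (gz) ".gz" else "")
    p2 <- paste0(base, "_2.fastq", if (gz) ".gz" else "")
    con1 <- if (gz) gzfile(p1, "w") else file(p1, "w")
    con2 <- if (gz) gzfile(p2, "w") else file(p2, "w")
    writeLines(reads1, con1); close(con1)
    writeLines(reads2, con2); close(con2)
    paths <- c(p1, p2)
  }
  list(pairs = pairs, reads1 = reads1, reads2 = reads2,
       linker_in_read1 = r1$has_linker, linker_in_read2 = r2$has_linker,
       fastq_paths = paths)
}

# sample exactly one element of x (safe for length-1 x, unlike sample())
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.random_dna <- function(n, width) {
  if (length(width) == 1L) width <- rep(width, n)
  vapply(width, function(w)
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""), "")
}
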