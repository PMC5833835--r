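test_that("tad_counts enumerates internal pairs and normalizes by depth", {
  n <- 10L
  bins <- bin_table(c(chr1 = n * 40000L), 40000L)
  ones <- contact_matrix(matrix(1, n, n), bins, 40000L)
  tads <- data.frame(chrom = "chr1", start = 0L, end = 3L * 40000L,
                     tad_id = "t1")
  raw <- tad_counts(ones, tads, normalize = FALSE)
  expect_equal(raw$internal, 3)                 # pairs (1,2), (1,3), (2,3)
  expect_equal(raw$external, 3 * 7)             # 3 inside x 7 outside

  whole <- data.frame(chrom = "chr1", start = 0L, end = n * 40000L,
                      tad_id = "all")
  expect_equal(tad_counts(ones, whole, normalize = FALSE)$external, 0)

  doubled <- contact_matrix(2 * ones$counts, bins, 40000L)
  expect_equal(tad_counts(ones, tads)$internal,
               tad_counts(doubled, tads)$internal)

  tiny <- data.frame(chrom = "chr1", start = 0L, end = 40000L, tad_id = "t0")
  expect_warning(tc <- tad_counts(ones, tiny, normalize = FALSE), "fewer than 2")
  expect_equal(tc$internal, 0)
})

test_that("internal/external/outside masses are conserved per chromosome", {
  cfg <- small_config(seed = 21)
  tr <- generate_truth(cfg)
  m <- simulate_contact_maps(tr, cfg)$cond1$rep1
  tc <- tad_counts(m, tr$tads, normalize = FALSE)
  # TADs tile the chromosome, so internal + external/2 covers every
  # off-diagonal intra cell except cross-TAD pairs; check the weaker exact
  # identity: sum(internal) + sum(external)/2 + cross-TAD mass = total
  total_offdiag <- matrix_mass(m, intra_only = TRUE) - sum(diag(m$counts))
  cross <- 0
  tad_of <- rep(NA_character_, nrow(m$bins))
  for (k in seq_len(nrow(tr$tads))) {
    mid <- (m$bins$start + m$bins$end) %/% 2
    sel <- m$bins$chrom == tr$tads$chrom[k] & mid >= tr$tads$start[k] &
      mid < tr$tads$end[k]
    tad_of[sel] <- tr$tads$tad_id[k]
  }
  ut <- which(upper.tri(m$counts), arr.ind = TRUE)
  same_chrom <- m$bins$chrom[ut[, 1]] == m$bins$chrom[ut[, 2]]
  diff_tad <- tad_of[ut[, 1]] != tad_of[ut[, 2]]
  cross <- sum(m$counts[ut[same_chrom & diff_tad, , drop = FALSE]])
  expect_equal(sum(tc$internal) + cross, total_offdiag)
  expect_equal(sum(tc$external), 2 * cross)  # each cross pair external to both
})

test_that("empirical p-values follow the rank formula and stay in (0, 1]", {
  cfg <- small_config(seed = 22)
  tr <- generate_truth(cfg)
  maps <- simulate_contact_maps(tr, cfg)
  # identical matrices across all samples: every fold change 0, p must be 1
  m <- maps$cond1$rep1
  tt_null <- tad_foldchange_test(list(m, m), list(m, m), tr$tads)
  expect_true(all(tt_null$p_internal_1 == 1))
  expect_false(any(tt_null$significant))

  tt <- tad_foldchange_test(maps$cond1, maps$cond2, tr$tads)
  pcols <- grep("^p_", names(tt), value = TRUE)
  for (pc in pcols) {
    expect_true(all(tt[[pc]] > 0 & tt[[pc]] <= 1))
  }
  expect_error(tad_foldchange_test(maps$cond1[1], maps$cond2, tr$tads),
               "2 replicates")
})

test_that("an observation beyond every background value hits the add-one floor", {
  # craft matrices where one TAD doubles in condition 2 while replicates agree
  n <- 60L
  bins <- bin_table(c(chr1 = n * 40000L), 40000L)
  tads <- data.frame(chrom = "chr1",
                     start = seq(0L, (n - 6L) * 40000L, by = 6L * 40000L))
  tads$end <- tads$start + 6L * 40000L
  tads$tad_id <- paste0("t", seq_len(nrow(tads)))
  base <- matrix(100, n, n)
  mk <- function(mult_first_tad = 1) {
    cnt <- base
    cnt[1:6, 1:6] <- cnt[1:6, 1:6] * mult_first_tad
    contact_matrix(cnt, bins, 40000L)
  }
  tt <- tad_foldchange_test(list(mk(), mk()), list(mk(4), mk(4)), tads)
  n_bg <- 2L * nrow(tads)
  expect_equal(tt$p_internal_1[1], 1 / (n_bg + 1))
  expect_equal(tt$p_internal_2[1], 1 / (n_bg + 1))
  expect_true(tt$significant[1])
})

test_that("sigma categories equal direct z-score binning", {
  expect_error(sigma_categories(c(1)), "at least 2")
  expect_error(sigma_categories(c(1, 1, 1)), "zero standard deviation")

  set.seed(30)
  x <- rnorm(200)
  got <- sigma_categories(x)
  z <- (x - mean(x)) / sd(x)
  edges <- c(-2, -1, -0.5, 0.5, 1, 2)
  want <- vapply(z, function(v) sum(v >= edges) + 1L, 0L)
  expect_equal(got, want)
  # central and extreme values land in the expected categories
  y <- c(rep(0, 9), 10)            # outlier z = 9/sqrt(10) > 2
  expect_equal(sigma_categories(y)[10], 7L)
  expect_true(all(sigma_categories(y)[1:9] == 4L))
})

test_that("DEG distribution across categories is well formed and enriched", {
  # unit-level contract on a crafted table
  tads <- data.frame(tad_id = c("t1", "t2"), chrom = "chr1",
                     start = c(0L, 500L), end = c(500L, 1000L),
                     category = c(7L, 1L))
  genes <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      tss = c(10L, 600L, 700L, 5L),
                      de_status = factor(c("up", "down", "stable", "up"),
                                         levels = c("up", "down", "stable")))
  dist <- deg_category_distribution(tads, genes)
  r7 <- dist[dist$category == "7", ]
  expect_equal(r7$n_up, 1L)
  expect_equal(r7$p_up, 1)
  r1 <- dist[dist$category == "1", ]
  expect_equal(r1$n_down, 1L)
  expect_equal(r1$p_down + r1$p_stable + r1$p_up, 1)
  expect_equal(dist$n_genes[dist$category == "no_TAD"], 1L)
  expect_equal(dist$n_genes[dist$category == "total"], 3L)

  # end-to-end: boosted TADs with coupled up-genes enrich the top categories
  cfg <- small_config(seed = 23, frac_boosted_tads = 0.25,
                      n_planted_gain = 0, n_planted_loss = 0,
                      n_expr_reps = 4L)
  tr <- generate_truth(cfg)
  maps <- simulate_contact_maps(tr, cfg)
  pe <- simulate_peaks_expression(tr, cfg)
  tt <- tad_foldchange_test(maps$cond1, maps$cond2, tr$tads)
  tt$category <- sigma_categories(tt$log2fc_internal)
  genes <- classify_degs(pe$expression)
  genes$chrom <- pe$expression$chrom
  dist2 <- deg_category_distribution(tt, genes)
  top <- dist2[dist2$category %in% c("6", "7"), ]
  total <- dist2[dist2$category == "total", ]
  expect_gt(sum(top$n_up) / max(1, sum(top$n_genes)), total$p_up)
})

test_that("boundary stability counts nearest boundaries within tolerance", {
  tads <- data.frame(chrom = "chr1", start = c(0L, 400000L, 900000L),
                     end = c(400000L, 900000L, 1500000L))
  bs <- boundary_stability(tads, tads)
  expect_equal(bs$fraction_stable, 1.0)

  shifted <- tads
  shifted$start <- shifted$start + 160000L
  shifted$end <- shifted$end + 160000L
  expect_lt(boundary_stability(tads, shifted, tolerance = 40000L)$fraction_stable, 1)
  expect_equal(boundary_stability(tads, shifted, tolerance = 200000L)$fraction_stable, 1.0)

  set.seed(31)
  t1 <- data.frame(chrom = "chr1", start = sort(sample.int(1e6, 10)) )
  t1$end <- t1$start + 1000L
  t2 <- data.frame(chrom = "chr1", start = sort(sample.int(1e6, 8)))
  t2$end <- t2$start + 1000L
  bs2 <- boundary_stability(t1, t2, tolerance = 5000L)
  b1 <- sort(unique(c(t1$start, t1$end)))
  b2 <- sort(unique(c(t2$start, t2$end)))
  want <- mean(vapply(b1, function(x) min(abs(b2 - x)) <= 5000L, TRUE))
  expect_equal(bs2$fraction_stable, want)

  expect_error(boundary_stability(tads[0L, ], tads), "empty")
})
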