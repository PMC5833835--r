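test_that("fisher_enrichment equals exhaustive hypergeometric enumeration", {
  flat <- fisher_enrichment(10, 10, 10, 10, alternative = "two.sided")
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  diag5 <- fisher_enrichment(5, 0, 0, 5, alternative = "greater")
  expect_equal(diag5$p_value, 1 / choose(10, 5))
  expect_equal(diag5$odds_ratio, Inf)

  set.seed(19)
  for (rep in 1:20) {
    tb <- sample.int(16, 4, replace = TRUE) - 1L  # margins <= 30
    got <- fisher_enrichment(tb[1], tb[2], tb[3], tb[4],
                             alternative = "greater")
    want <- oracle_fisher_greater(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got$p_value, want, tolerance = 1e-10)
  }
  expect_error(fisher_enrichment(-1, 2, 3, 4), "non-negative")
})

test_that("mann_whitney exact branch equals full permutation enumeration", {
  same <- mann_whitney(c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5))
  expect_gt(same$p_value, 0.99)

  shifted <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(shifted$U, 0)
  expect_equal(shifted$p_value, 0.1)  # 2 / choose(6, 3)

  set.seed(20)
  for (rep in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    g1 <- round(rnorm(n1), 3); g2 <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(g1, g2))) next
    got <- mann_whitney(g1, g2)$p_value
    want <- oracle_mwu_two_sided(g1, g2)
    expect_equal(got, want, tolerance = 1e-10)
  }

  set.seed(21)
  big <- mann_whitney(rnorm(500), rnorm(500, 1))
  expect_lt(big$p_value, 1e-10)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("region signal fold changes match direct recomputation", {
  s1 <- rep(50, 100)
  regions <- list(1:10, 40:60, 95:100)
  expect_equal(region_signal_foldchange(s1, 2 * s1, regions),
               rep(1, 3), tolerance = 0.01)  # large-sum limit
  expect_equal(region_signal_foldchange(s1, s1, regions), rep(0, 3))

  set.seed(22)
  a <- runif(100); b <- runif(100)
  got <- region_signal_foldchange(a, b, regions, eps = 0.5)
  want <- vapply(regions, function(idx)
    log2((sum(b[idx]) + 0.5) / (sum(a[idx]) + 0.5)), 0)
  expect_equal(got, want)
  expect_error(region_signal_foldchange(a, b, list(99:101)), "outside")
})

test_that("DEG enrichment among interaction genes uses the right margins", {
  all_genes <- data.frame(
    gene_id = paste0("g", 1:100),
    de_status = factor(c(rep("up", 10), rep("down", 10), rep("stable", 80)),
                       levels = c("up", "down", "stable")))
  gain <- paste0("g", 1:8)      # all up
  loss <- paste0("g", c(11:14, 95))
  out <- interaction_deg_enrichment(gain, loss, all_genes)
  expect_equal(out$table$n_up[out$table$set == "Gain"], 8L)
  expect_equal(out$table$n_down[out$table$set == "Loss"], 4L)
  expect_lt(out$fisher$p_value[out$fisher$set == "Gain"], 0.05)
  # margins re-derivable: involved + uninvolved DEGs = all DEGs
  expect_equal(out$table$n_up + out$table$n_down +
                 out$table$n_stable, out$table$n)
  expect_error(interaction_deg_enrichment("nope", loss, all_genes), "unknown")
})

test_that("null resampling keeps DEG enrichment p-values unremarkable", {
  set.seed(23)
  all_genes <- data.frame(
    gene_id = paste0("g", 1:500),
    de_status = factor(sample(c("up", "down", "stable"), 500, TRUE,
                              prob = c(0.1, 0.1, 0.8)),
                       levels = c("up", "down", "stable")))
  ps <- replicate(50, {
    pick <- sample(all_genes$gene_id, 40)
    interaction_deg_enrichment(pick[1:20], pick[21:40],
                               all_genes)$fisher$p_value[1]
  })
  # under the null, about half the one-sided p-values sit above 0.5
  expect_gt(mean(ps > 0.4), 0.3)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("peak enrichment tables are maximal under full coupling", {
  cfg <- small_config(seed = 18, coupling_prob = 1)
  pip <- run_gain_loss_pipeline(cfg)
  pe <- pip$peaks_expr
  # condition-specific distal peaks from the replicate-intersected sets
  d1 <- convincing_peaks(pe, "distal", "cond1")
  d2 <- convincing_peaks(pe, "distal", "cond2")
  op <- overlap_partition(d1, d2)
  enr <- peak_region_enrichment(op$specific_a, op$specific_b,
                                pip$annotations, pip$calls)
  if (!is.null(enr$regulatory_region)) {
    tab <- enr$regulatory_region$table
    # Gain regulatory bins carry condition-2-specific peaks, never cond-1
    expect_equal(tab["Gain", "cond1_specific"], 0)
    expect_equal(tab["Loss", "cond2_specific"], 0)
    expect_lt(enr$regulatory_region$p_value, 0.01)
  } else {
    fail("regulatory-region table missing despite planted calls")
  }
  # margins conserved: cells count called bins with specific peaks
  gain_bins <- unique(pip$calls$reg_bin[pip$calls$call == "Gain"])
  expect_lte(sum(enr$regulatory_region$table["Gain", ]), length(gain_bins))

  no_calls <- pip$calls[pip$calls$call == "NS", ]
  w <- capture_warnings(
    peak_region_enrichment(op$specific_a, op$specific_b,
                           pip$annotations, no_calls))
  expect_true(any(grepl("empty", w)))
})

test_that("network hub degrees equal a brute-force incidence recount", {
  edges <- data.frame(source = c("hub", "hub", "hub", "a", "x"),
                      target = c("a", "b", "c", "b", "y"))
  out <- network_hub_degrees(edges, c("hub", "a", "b", "c", "isolated"))
  expect_equal(out$node[1], "hub")
  expect_equal(out$degree[1], 3)
  expect_equal(out$degree[out$node == "isolated"], 0)

  set.seed(24)
  nodes <- paste0("n", 1:30)
  rnd <- unique(data.frame(source = sample(nodes, 200, TRUE),
                           target = sample(nodes, 200, TRUE)))
  focus <- sample(nodes, 15)
  got <- network_hub_degrees(rnd, focus)
  sub <- rnd[rnd$source %in% focus & rnd$target %in% focus, ]
  want <- vapply(focus, function(nd) sum(sub$source == nd) +
                   sum(sub$target == nd), 0)
  expect_equal(setNames(got$degree, got$node)[focus], want)
})
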