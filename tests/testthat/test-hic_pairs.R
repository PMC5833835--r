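lk <- linker_config()

test_that("trim_linker keeps the 5' fragment and flags edge placements", {
  reads <- c(paste0("AAAA", lk$forward, "CCCC"),   # linker mid-read
             "ACGTACGTACGTACGTACGTACGT",           # no linker
             paste0(lk$forward, "CCCC"),           # linker at read start
             paste0("TTTT", lk$reverse, "GGGG"),   # reverse orientation
             paste0("AC", lk$forward, "GG", lk$forward, "TT"))  # two copies
  cfg <- linker_config(min_fragment = 4L)
  out <- trim_linker(reads, config = cfg)
  expect_equal(out$fragment[1], "AAAA")
  expect_true(out$linker_found[1])
  expect_false(out$discarded[1])

  expect_equal(out$fragment[2], reads[2])
  expect_false(out$linker_found[2])

  expect_equal(out$fragment[3], "")
  expect_true(out$linker_found[3])
  expect_true(out$discarded[3])           # empty 5' flank

  expect_equal(out$fragment[4], "TTTT")
  expect_true(out$linker_found[4])

  # leftmost copy used; the kept fragment never contains a full linker
  expect_equal(out$fragment[5], "AC")
  expect_false(any(grepl(lk$forward, out$fragment, fixed = TRUE) |
                     grepl(lk$reverse, out$fragment, fixed = TRUE)))
})

test_that("trim_linker slices qualities in register and honors mismatches", {
  read <- paste0("AAAA", lk$forward, "CCCC")
  qual <- paste(rep("F", nchar(read)), collapse = "")
  out <- trim_linker(read, quals = qual, config = linker_config(min_fragment = 2L))
  expect_equal(nchar(out$qual), nchar(out$fragment))

  mutated <- sub("^CGCG", "CGCA", lk$forward)  # one mismatch
  read_mm <- paste0("AAAAAA", mutated, "CCCC")
  exact <- trim_linker(read_mm, config = linker_config(min_fragment = 2L))
  expect_false(exact$linker_found)
  fuzzy <- trim_linker(read_mm,
                       config = linker_config(max_mismatches = 1L,
                                              min_fragment = 2L))
  expect_true(fuzzy$linker_found)
  expect_equal(fuzzy$fragment, "AAAAAA")
})

test_that("dedupe_pairs collapses exact and mate-swapped duplicates", {
  p <- data.frame(chrom1 = "chr1", pos1 = 100L, strand1 = "+",
                  chrom2 = "chr1", pos2 = 900L, strand2 = "-")
  expect_equal(nrow(dedupe_pairs(rbind(p, p))), 1L)

  swapped <- data.frame(chrom1 = "chr1", pos1 = 900L, strand1 = "-",
                        chrom2 = "chr1", pos2 = 100L, strand2 = "+")
  expect_equal(nrow(dedupe_pairs(rbind(p, swapped))), 1L)

  set.seed(3)
  n <- 1000L
  rand <- data.frame(chrom1 = sample(c("chr1", "chr2"), n, TRUE),
                     pos1 = sample.int(1e6, n, TRUE),
                     strand1 = sample(c("+", "-"), n, TRUE),
                     chrom2 = sample(c("chr1", "chr2"), n, TRUE),
                     pos2 = sample.int(1e6, n, TRUE),
                     strand2 = sample(c("+", "-"), n, TRUE))
  dup_idx <- sample.int(n, 100L)
  with_dups <- rbind(rand, rand[dup_idx, ])
  # hash-set oracle on canonicalized tuples
  canon <- function(df) {
    swap <- df$chrom1 > df$chrom2 | (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
    key1 <- ifelse(swap, paste(df$chrom2, df$pos2, df$strand2), paste(df$chrom1, df$pos1, df$strand1))
    key2 <- ifelse(swap, paste(df$chrom1, df$pos1, df$strand1), paste(df$chrom2, df$pos2, df$strand2))
    paste(key1, key2)
  }
  expect_equal(nrow(dedupe_pairs(with_dups)),
               length(unique(canon(with_dups))))
})

test_that("span threshold is recovered from planted artifact geometry", {
  cfg <- small_config(seed = 3, n_chroms = 2L)
  tr <- generate_truth(cfg)
  rp <- simulate_read_pairs(tr, cfg, n_pairs = 20000, span_threshold = 3000L)
  est <- estimate_span_threshold(rp$pairs)
  # within one log-spaced bin of the planted 3 kb threshold
  bin_ratio <- (max(rp$pairs$pos2 - rp$pairs$pos1) / 100)^(1 / 30)
  expect_lt(est, 3000 * bin_ratio)
  expect_gt(est, 3000 / bin_ratio)

  # orientation-balanced pairs at every span: first informative bin edge
  set.seed(8)
  n <- 8000L
  span <- round(exp(runif(n, log(200), log(1e6))))
  pos1 <- sample.int(1e7, n, TRUE)
  bal <- data.frame(chrom1 = "chr1", pos1 = pos1,
                    strand1 = sample(c("+", "-"), n, TRUE),
                    chrom2 = "chr1", pos2 = pos1 + span,
                    strand2 = sample(c("+", "-"), n, TRUE))
  est_bal <- estimate_span_threshold(bal)
  expect_lt(est_bal, 500)

  empty <- bal[0L, ]
  expect_warning(est0 <- estimate_span_threshold(empty), "fallback")
  expect_equal(est0, 3000L)
})

test_that("classify_pairs follows the span/strand geometry rules", {
  mk <- function(p1, s1, p2, s2, c1 = "chr1", c2 = "chr1") {
    data.frame(chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2)
  }
  expect_equal(classify_pairs(mk(1000L, "+", 2000L, "-"), 3000L)$class,
               "full_segment")
  expect_equal(classify_pairs(mk(1000L, "-", 2000L, "+"), 3000L)$class,
               "self_ligation")
  expect_equal(classify_pairs(mk(1000L, "+", 2000L, "+"), 3000L)$class,
               "intra")  # same-strand short pairs require a ligation
  expect_equal(classify_pairs(mk(1000L, "+", 1001000L, "-"), 3000L)$class,
               "intra")
  expect_equal(classify_pairs(mk(1000L, "+", 2000L, "-", "chr1", "chr2"),
                              3000L)$class, "inter")

  # exhaustive, deterministic, order-independent
  set.seed(12)
  n <- 500L
  rand <- data.frame(chrom1 = sample(c("chr1", "chr2"), n, TRUE),
                     pos1 = sample.int(1e6, n, TRUE),
                     strand1 = sample(c("+", "-"), n, TRUE),
                     chrom2 = sample(c("chr1", "chr2"), n, TRUE),
                     pos2 = sample.int(1e6, n, TRUE),
                     strand2 = sample(c("+", "-"), n, TRUE))
  cl <- classify_pairs(rand, 3000L)
  expect_true(all(cl$class %in% c("full_segment", "self_ligation",
                                  "intra", "inter")))
  perm <- sample.int(n)
  cl_perm <- classify_pairs(rand[perm, ], 3000L)
  expect_equal(cl_perm$class, cl$class[perm])

  stats <- pair_class_stats(cl)
  expect_equal(sum(stats$count), n)
  expect_equal(sum(stats$fraction), 1)
})
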