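# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the functions they
# verify.

# all-pairs overlap scan: amount of shared bases between [s1,e1) and [s2,e2)
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

oracle_common_flags <- function(set_a, set_b, min_overlap) {
  vapply(seq_len(nrow(set_a)), function(i) {
    any(vapply(seq_len(nrow(set_b)), function(j) {
      set_a$chrom[i] == set_b$chrom[j] &&
        oracle_overlap_bp(set_a$start[i], set_a$end[i],
                          set_b$start[j], set_b$end[j]) >= min_overlap
    }, TRUE))
  }, TRUE)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# one-sided (greater) Fisher p by hypergeometric enumeration over tables
# with the same margins and a' >= a
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  amax <- min(m, k)
  sum(vapply(a:amax, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, 0))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_two_sided <- function(g1, g2) {
  n1 <- length(g1)
  all_vals <- c(g1, g2)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(g1, g2)
  n <- length(all_vals)
  combos <- combn(n, n1)
  u_all <- apply(combos, 2L, function(idx) {
    u_stat(all_vals[idx], all_vals[-idx])
  })
  mu <- n1 * (n - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# random interval fixture on a toy genome
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(500L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             name = paste0("iv", seq_len(n)), signal = runif(n))
}
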