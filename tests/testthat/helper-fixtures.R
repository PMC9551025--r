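# Shared fixtures and independent oracles used across the suite.

# Exhaustive hypergeometric tail oracle in plain (non-log) arithmetic:
# P(X >= k) as a direct ratio of binomial coefficients. Independent of the
# package's log-space summation path.
enum_hyper_tail <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Rank-permutation oracle for the two-group log-rank test: permutes group
# labels and returns the fraction of permuted statistics at least as large
# as the observed one.
perm_logrank_p <- function(group, clinical, B = 1e4, seed = 1) {
  obs <- logrank_test(group, clinical)$statistic
  stats <- withr::with_seed(seed, replicate(B, {
    logrank_test(unname(sample(group)), clinical)$statistic
  }))
  mean(stats >= obs - 1e-12)
}

# Tiny deterministic count fixture
make_small_counts <- function() {
  m <- matrix(c(10, 100, 40,
                12, 110, 38,
                50,  90, 45,
                55,  95, 41), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  count_matrix(m, c(s1 = "case", s2 = "case", s3 = "control", s4 = "control"))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
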