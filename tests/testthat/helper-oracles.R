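# Independent brute-force oracles used to cross-check the package
# implementations. Deliberately written as literal loops over the defining
# formulas, sharing no code with the package internals.

# normalized Shannon entropy by direct summation over observed counts
oracle_entropy <- function(counts, b) {
  N <- sum(counts)
  h <- 0
  for (n in counts[counts > 0]) h <- h - (n / N) * log(n / N, base = 2)
  h / b
}

# Gini index with k fixed at 2^b, zeros for unobserved, non-decreasing order
oracle_gini <- function(counts, b) {
  k <- 2^b
  n <- sort(c(counts[counts > 0], rep(0, k - sum(counts > 0))))
  acc <- 0
  for (i in 1:k) acc <- acc + (k + 1 - i) * n[i]
  (k + 1 - 2 * acc / sum(n)) / (k - 1)
}

# all multisets of positive counts summing to N with at most 'parts' parts
# (non-increasing recursion)
oracle_count_multisets <- function(N, parts, maxval = N) {
  if (N == 0) return(list(integer(0)))
  if (parts == 0) return(list())
  out <- list()
  for (v in seq_len(min(N, maxval))) {
    for (rest in oracle_count_multisets(N - v, parts - 1, v))
      out[[length(out) + 1L]] <- c(v, rest)
  }
  out
}

# exact permutation p-value by exhaustive enumeration of all assignments of
# the pooled (distinguishable) reads into a group of size na
oracle_perm_p <- function(codes_a, codes_b, b) {
  ent <- function(v) {
    tab <- table(v)
    oracle_entropy(as.integer(tab), b)
  }
  obs <- abs(ent(codes_a) - ent(codes_b))
  pool <- c(codes_a, codes_b)
  na <- length(codes_a)
  picks <- utils::combn(length(pool), na, simplify = FALSE)
  hits <- 0
  for (ix in picks) {
    stat <- abs(ent(pool[ix]) - ent(pool[-ix]))
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  hits / length(picks)
}

# random pattern_counts for property tests
random_pc <- function(b = 4, max_patterns = 2^b, max_total = 40) {
  k <- sample.int(max_patterns, 1)
  codes <- sample.int(2^b, k) - 1L
  counts <- stats::setNames(
    as.integer(sample.int(max(1, max_total %/% k), k, replace = TRUE)),
    codes)
  pattern_counts(counts, b = b)
}
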