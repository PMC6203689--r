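# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

entropy_of_codes <- function(codes, b) {
  n <- tabulate(factor(codes))
  p <- n / length(codes)
  sum(-p * log2(p)) / b
}

perm_result <- function(observed, exceed, n, seed, exact) {
  p <- if (exact) exceed / n else (1 + exceed) / (1 + n)
  structure(list(observed = observed, p_value = p, n_permutations = n,
                 seed = seed, exact = exact),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed |diff| = %.6f, p = %.4g (%s, %d %s)\n",
              x$observed, x$p_value,
              if (x$exact) "exact enumeration" else paste("seed", x$seed),
              x$n_permutations,
              if (x$exact) "partitions" else "permutations"))
  invisible(x)
}

#' Permutation test for an entropy difference between two read groups
#'
#' Tests whether two segments (or two samples at one segment) differ in
#' normalized Shannon entropy. The statistic is the absolute entropy
#' difference `|H(a) - H(b)|`. Under the null the group labels are
#' exchangeable, so the pooled pattern observations are randomly
#' re-partitioned into groups of the original sizes and the statistic is
#' recomputed. With `exact = TRUE` every distinct re-partition (all
#' `choose(Na + Nb, Na)` assignments of the pooled reads) is enumerated
#' and the p-value is the exact fraction with a statistic at least as
#' large as observed. Otherwise `n_perm` random re-partitions are drawn
#' under `seed` and the add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)` is used, which
#' never returns 0 (claiming p < 0.001 hence needs `n_perm >= 999`).
#'
#' @param a,b [pattern_counts()] with the same `b` and `N >= 1`.
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed RNG seed; recorded in the result. The caller's RNG state
#'   is left untouched.
#' @param exact enumerate all re-partitions instead of sampling; only
#'   feasible for small pooled read counts.
#' @return An object of class `permutation_result`: `observed`,
#'   `p_value`, `n_permutations`, `seed`, `exact`.
#' @export
permutation_test_entropy <- function(a, b, n_perm = 1000L, seed = 1L,
                                     exact = FALSE) {
  stopifnot(inherits(a, "pattern_counts"), inherits(b, "pattern_counts"))
  if (a$b != b$b) stop("groups have different sites per segment")
  if (a$N < 1L || b$N < 1L) stop("both groups need at least one read")
  bb <- a$b
  ca <- rep(as.integer(names(a$counts)), a$counts)
  cb <- rep(as.integer(names(b$counts)), b$counts)
  pool <- c(ca, cb)
  na <- length(ca)
  obs <- abs(entropy_of_codes(ca, bb) - entropy_of_codes(cb, bb))
  tol <- 1e-12
  stat <- function(ia) abs(entropy_of_codes(pool[ia], bb) -
                           entropy_of_codes(pool[-ia], bb))
  if (exact) {
    picks <- utils::combn(length(pool), na, simplify = FALSE)
    exceed <- sum(vapply(picks, stat, 0) >= obs - tol)
    return(perm_result(obs, exceed, length(picks), seed, TRUE))
  }
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  perm <- with_seed(seed, replicate(n_perm, stat(sample.int(length(pool),
                                                            na))))
  perm_result(obs, sum(perm >= obs - tol), n_perm, seed, FALSE)
}

#' Permutation test for a difference in mean segment-level values
#'
#' Region-level companion of [permutation_test_entropy()]: when comparing
#' two samples over a gene region, the exchangeable unit is the segment,
#' not the read. The statistic is the absolute difference of group means
#' of per-segment values (entropy or methylation level); values are
#' re-partitioned between the two groups.
#'
#' @param a,b numeric vectors of per-segment values.
#' @inheritParams permutation_test_entropy
#' @return An object of class `permutation_result`.
#' @export
permutation_test_values <- function(a, b, n_perm = 1000L, seed = 1L,
                                    exact = FALSE) {
  if (!length(a) || !length(b)) stop("both groups need at least one value")
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-12
  stat <- function(ia) abs(mean(pool[ia]) - mean(pool[-ia]))
  if (exact) {
    picks <- utils::combn(length(pool), na, simplify = FALSE)
    exceed <- sum(vapply(picks, stat, 0) >= obs - tol)
    return(perm_result(obs, exceed, length(picks), seed, TRUE))
  }
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  perm <- with_seed(seed, replicate(n_perm, stat(sample.int(length(pool),
                                                            na))))
  perm_result(obs, sum(perm >= obs - tol), n_perm, seed, FALSE)
}

#' Bootstrap standard error of a mean
#'
#' Resamples the input values with replacement `n_boot` times and reports
#' the standard deviation of the replicate means as the standard error of
#' the mean — the error bars used for aggregated region-level methylation
#' level and entropy.
#'
#' @param values numeric vector (at least one value).
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return An object of class `bootstrap_result`: `mean`,
#'   `standard_error`, `n_replicates`, `seed`.
#' @export
bootstrap_se <- function(values, n_boot = 1000L, seed = 1L) {
  if (!length(values)) stop("no values to bootstrap")
  if (n_boot < 2L) stop("'n_boot' must be at least 2")
  means <- with_seed(seed, replicate(n_boot,
    mean(values[sample.int(length(values), replace = TRUE)])))
  structure(list(mean = mean(values), standard_error = stats::sd(means),
                 n_replicates = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: mean = %.6f, SE = %.6f (%d replicates, seed %d)\n",
              x$mean, x$standard_error, x$n_replicates, x$seed))
  invisible(x)
}
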