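#' Heterogeneity and methylation-level statistics of a pattern multiset
#'
#' Three per-segment statistics over the distribution of read-level
#' methylation patterns:
#'
#' \describe{
#'   \item{`shannon_entropy`}{Normalized Shannon entropy
#'     \deqn{H = \frac{1}{b}\sum_{i=1}^{k} -\frac{n_i}{N}\log_2\frac{n_i}{N}}
#'     where \eqn{n_i} are the counts of the \eqn{k} observed patterns,
#'     \eqn{N = \sum n_i}, and \eqn{b} the number of CpG sites per
#'     pattern. The \eqn{1/b} normalization maps it to \eqn{[0, 1]}: 0
#'     when a single pattern is observed, 1 when reads are spread evenly
#'     over all \eqn{2^b} possible patterns. Only observed patterns enter
#'     the sum (the \eqn{0\log 0} terms vanish in the limit).}
#'   \item{`gini_index`}{Evenness statistic over the full pattern space:
#'     \deqn{G = \frac{1}{k-1}\left[k + 1 -
#'       2\frac{\sum_{i=1}^{k}(k+1-i)\,n_i}{\sum_{i=1}^{k} n_i}\right]}
#'     with \eqn{k} fixed at \eqn{2^b} (16 for 4-site segments), counts
#'     indexed in non-decreasing order and unobserved patterns entered as
#'     \eqn{n_i = 0}. Equals 1 when one pattern carries all reads, 0 when
#'     all \eqn{2^b} patterns are equally frequent.}
#'   \item{`methylation_level`}{The fraction of methylated cytosine among
#'     all cytosine calls, \eqn{^mC/(^mC + C)}: the mean proportion of
#'     methylated sites per read, weighted by read counts.}
#' }
#'
#' Entropy and Gini depend only on the count multiset \eqn{\{n_i\}} and
#' `b`, never on which patterns carry the counts; the methylation level
#' depends on the pattern identities.
#'
#' @param pc a [pattern_counts()] object with `N >= 1`.
#' @return A single numeric value in `[0, 1]`.
#' @examples
#' shannon_entropy(pattern_counts(c(`0` = 16)))            # 0
#' shannon_entropy(pattern_counts(setNames(rep(1, 16), 0:15)))  # 1
#' gini_index(pattern_counts(c(MMMM = 8, UUUU = 8)))       # 14/15
#' methylation_level(pattern_counts(c(MMUU = 5, UUUU = 5)))  # 0.25
#' @export
shannon_entropy <- function(pc) {
  stopifnot(inherits(pc, "pattern_counts"))
  if (pc$N < 1L) stop("no covering reads (N = 0)")
  p <- pc$counts / pc$N
  sum(-p * log2(p)) / pc$b
}

#' @rdname shannon_entropy
#' @export
gini_index <- function(pc) {
  stopifnot(inherits(pc, "pattern_counts"))
  if (pc$N < 1L) stop("no covering reads (N = 0)")
  k <- 2^pc$b
  n <- sort(c(pc$counts, rep(0L, k - pc$k)))  # zeros for unobserved
  (k + 1 - 2 * sum((k + 1 - seq_len(k)) * n) / sum(n)) / (k - 1)
}

#' @rdname shannon_entropy
#' @export
methylation_level <- function(pc) {
  stopifnot(inherits(pc, "pattern_counts"))
  if (pc$N < 1L) stop("no covering reads (N = 0)")
  m <- pattern_m_count(as.integer(names(pc$counts)), pc$b)
  sum(pc$counts * m) / (pc$N * pc$b)
}
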