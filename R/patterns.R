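#' Encode and decode methylation patterns
#'
#' A methylation pattern is the ordered methylated/unmethylated status of
#' `b` consecutive CpG sites observed on one sequencing read (or carried by
#' one epiallele). Patterns are stored canonically as integers in
#' `[0, 2^b)`: bit `j` (0-based, least significant first) is 1 iff site
#' `j`, counted 5' to 3' on the forward strand, is methylated.
#'
#' @param states character vector of single letters in `c("M", "U")`
#'   (methylated / unmethylated), 5' to 3', or a single string such as
#'   `"MMUU"`.
#' @param code integer pattern code in `[0, 2^b)`.
#' @param b number of CpG sites in the pattern.
#' @return `encode_pattern` returns the integer code; `decode_pattern`
#'   returns a single string of `M`/`U` letters of length `b`.
#' @examples
#' encode_pattern("MMUU")        # bits 0 and 1 set -> 3
#' decode_pattern(3L, b = 4)     # "MMUU"
#' @export
encode_pattern <- function(states) {
  if (length(states) == 1L && nchar(states) > 1L)
    states <- strsplit(states, "", fixed = TRUE)[[1L]]
  if (!all(states %in% c("M", "U")))
    stop("pattern states must be 'M' or 'U'")
  as.integer(sum((states == "M") * 2^(seq_along(states) - 1L)))
}

#' @rdname encode_pattern
#' @export
decode_pattern <- function(code, b) {
  stopifnot(b >= 1L, code >= 0L, code < 2^b)
  bits <- bitwAnd(code %/% 2L^(0:(b - 1L)), 1L)
  paste(ifelse(bits == 1L, "M", "U"), collapse = "")
}

# number of methylated sites in each integer pattern code (vectorized)
pattern_m_count <- function(codes, b) {
  m <- integer(length(codes))
  for (j in 0:(b - 1L)) m <- m + bitwAnd(codes %/% 2L^j, 1L)
  m
}

#' Construct a pattern-count multiset for one DNA segment
#'
#' Bundles the observed methylation-pattern counts of a segment of `b`
#' consecutive CpG sites with its coordinates. This is the common input of
#' [shannon_entropy()], [gini_index()], [methylation_level()] and the
#' filter cascade ([apply_filters()]).
#'
#' @param counts named non-negative integer vector; names are integer
#'   pattern codes (see [encode_pattern()]) or `M`/`U` strings. Zero counts
#'   are dropped.
#' @param b number of CpG sites per pattern (4 by default; 8 for
#'   concatenated epiallele pairs).
#' @param chrom,positions optional segment coordinates: chromosome name and
#'   the 0-based positions of the `b` CpG sites (strictly increasing).
#' @return An object of class `pattern_counts`: a list with elements
#'   `counts` (named by integer code, sorted by code), `b`, `N` (total
#'   reads), `k` (distinct observed patterns), `chrom`, `positions`.
#' @examples
#' pattern_counts(c(MMMM = 10, UUUU = 6))
#' @export
pattern_counts <- function(counts, b = 4L, chrom = NA_character_,
                           positions = NULL) {
  b <- as.integer(b)
  if (length(counts)) {
    nm <- names(counts)
    if (is.null(nm)) stop("'counts' must be named by pattern")
    codes <- suppressWarnings(as.integer(nm))
    if (anyNA(codes)) codes <- vapply(nm, encode_pattern, integer(1))
    if (any(codes < 0L | codes >= 2^b)) stop("pattern code out of [0, 2^b)")
    if (anyDuplicated(codes)) stop("duplicated patterns in 'counts'")
    counts <- as.integer(counts)
    if (any(counts < 0L)) stop("negative pattern count")
    keep <- counts > 0L
    counts <- counts[keep]
    codes <- codes[keep]
    o <- order(codes)
    counts <- stats::setNames(counts[o], codes[o])
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != b || is.unsorted(positions, strictly = TRUE))
      stop("'positions' must be ", b, " strictly increasing coordinates")
  }
  structure(
    list(counts = counts, b = b, N = sum(counts), k = length(counts),
         chrom = chrom, positions = positions),
    class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  loc <- if (!is.na(x$chrom) && !is.null(x$positions))
    sprintf(" %s:%d-%d", x$chrom, x$positions[1L],
            x$positions[x$b] + 2L) else ""
  cat(sprintf("pattern_counts%s  b=%d  N=%d  k=%d\n", loc, x$b, x$N, x$k))
  if (x$k) {
    pat <- vapply(as.integer(names(x$counts)), decode_pattern, "", b = x$b)
    print(stats::setNames(unname(x$counts), pat))
  }
  invisible(x)
}
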