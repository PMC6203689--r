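#' Read per-read CpG methylation calls
#'
#' Parses per-site methylation calls of individual sequencing reads into a
#' call table with one row per read-site call. Two dialects are supported:
#'
#' \describe{
#'   \item{`bismark_extractor`}{Whitespace-separated, 5 columns as written
#'     by the Bismark methylation extractor: read id, strand (`+`/`-`),
#'     chromosome, 1-based position, call letter. `Z` is a methylated CpG
#'     and `z` an unmethylated CpG; non-CpG context letters
#'     (`X`/`x`/`H`/`h`/`U`/`u`) are skipped. Positions are converted to
#'     0-based, and calls on the reverse-strand cytosine (the G of the
#'     forward-strand CpG) are reassigned to the forward-strand C one base
#'     to the left, so both strands report the same site.}
#'   \item{`simple_tsv`}{Tab- or whitespace-separated, 5 columns: read id,
#'     cell id, chromosome, 0-based forward-strand position of the CpG C,
#'     call (`M`/`U`).}
#' }
#'
#' @param path file to read (plain text).
#' @param dialect `"bismark_extractor"` or `"simple_tsv"`.
#' @param cell cell identifier attached to every read of a
#'   `bismark_extractor` file (one file per cell in single-cell mode);
#'   default `"bulk"`.
#' @return A data.frame with columns `read`, `cell`, `chrom`, `pos`
#'   (0-based forward-strand CpG position) and `call` (`"M"`/`"U"`).
#' @export
read_methylation_calls <- function(path,
                                   dialect = c("bismark_extractor",
                                               "simple_tsv"),
                                   cell = "bulk") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("call file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(read = character(0), cell = character(0),
                      chrom = character(0), pos = integer(0),
                      call = character(0))
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop("malformed line ", which(nf != 5L)[1L], " in ", path,
         ": expected 5 fields, got ", nf[nf != 5L][1L])
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  if (dialect == "bismark_extractor") {
    strand <- m[, 2L]
    if (!all(strand %in% c("+", "-")))
      stop("malformed line ", which(!strand %in% c("+", "-"))[1L], " in ",
           path, ": strand must be '+' or '-'")
    letter <- m[, 5L]
    known <- c("Z", "z", "X", "x", "H", "h", "U", "u")
    if (!all(letter %in% known))
      stop("unknown call letter '", letter[!letter %in% known][1L],
           "' at line ", which(!letter %in% known)[1L], " in ", path)
    keep <- letter %in% c("Z", "z")
    if (!any(keep)) return(empty)
    pos1 <- suppressWarnings(as.integer(m[keep, 4L]))
    if (anyNA(pos1))
      stop("malformed position at line ", which(keep)[is.na(pos1)][1L],
           " in ", path)
    pos <- pos1 - 1L                       # 1-based -> 0-based
    pos[strand[keep] == "-"] <- pos[strand[keep] == "-"] - 1L  # G -> C
    data.frame(read = m[keep, 1L], cell = cell, chrom = m[keep, 3L],
               pos = pos, call = ifelse(letter[keep] == "Z", "M", "U"))
  } else {
    call <- m[, 5L]
    if (!all(call %in% c("M", "U")))
      stop("unknown call letter '", call[!call %in% c("M", "U")][1L],
           "' at line ", which(!call %in% c("M", "U"))[1L], " in ", path)
    pos <- suppressWarnings(as.integer(m[, 4L]))
    if (anyNA(pos))
      stop("malformed position at line ", which(is.na(pos))[1L], " in ",
           path)
    data.frame(read = m[, 1L], cell = m[, 2L], chrom = m[, 3L],
               pos = pos, call = call)
  }
}

#' Tally read-level methylation patterns over one segment
#'
#' A read contributes one methylation pattern to a segment iff it carries
#' an unambiguous `M`/`U` call at every one of the segment's CpG sites.
#' Reads missing a call at any site are excluded; so are reads with
#' conflicting duplicate calls at a site (they are not arbitrated).
#'
#' @param calls call table as returned by [read_methylation_calls()].
#' @param segment either a one-row segment data.frame from
#'   [make_segments()] or a numeric vector of the segment's CpG positions
#'   (then `chrom` must be given unless the calls span one chromosome).
#' @param chrom chromosome of the segment when `segment` is a bare
#'   position vector.
#' @return A [pattern_counts()] for the segment (possibly with `N = 0`).
#' @export
collect_patterns <- function(calls, segment, chrom = NULL) {
  if (is.data.frame(segment)) {
    stopifnot(nrow(segment) == 1L)
    positions <- segment$positions[[1L]]
    chrom <- segment$chrom
  } else {
    positions <- as.integer(segment)
    if (is.null(chrom)) {
      chrom <- unique(calls$chrom)
      if (length(chrom) > 1L)
        stop("'chrom' required: calls span multiple chromosomes")
      if (!length(chrom)) chrom <- NA_character_
    }
  }
  sub <- calls[calls$chrom %in% chrom & calls$pos %in% positions, ,
               drop = FALSE]
  counts <- tally_patterns(sub$read, match(sub$pos, positions),
                           sub$call == "M", length(positions))
  pattern_counts(counts, b = length(positions), chrom = chrom,
                 positions = positions)
}

# Core tally: read ids, 1-based site slot within the segment, logical
# methylated, number of slots b. Returns named count vector (integer
# pattern codes). Reads with a conflicting duplicate call at a slot are
# dropped; consistent duplicates collapse to one call.
tally_patterns <- function(read, slot, meth, b) {
  if (!length(read)) return(stats::setNames(integer(0), character(0)))
  key <- paste(read, slot)
  dup <- !duplicated(key)
  agree <- !as.logical(stats::ave(meth, key,
                                  FUN = function(x) length(unique(x)) > 1))
  bad_reads <- unique(read[!agree])
  keep <- dup & agree & !(read %in% bad_reads)
  read <- read[keep]; slot <- slot[keep]; meth <- meth[keep]
  if (!length(read)) return(stats::setNames(integer(0), character(0)))
  nsites <- tapply(slot, read, length)
  full <- names(nsites)[nsites == b]
  if (!length(full)) return(stats::setNames(integer(0), character(0)))
  keep <- read %in% full
  code <- tapply(as.integer(meth[keep]) * 2L^(slot[keep] - 1L),
                 read[keep], sum)
  tab <- table(code)
  stats::setNames(as.integer(tab), names(tab))
}

#' Filter configuration for the pattern filter cascade
#'
#' Thresholds of the error-pattern filter applied to each segment's
#' pattern counts: a segment needs at least `min_coverage` fully covering
#' reads to be evaluated at all; patterns supported by fewer than
#' `min_pattern_reads` reads, or with frequency below
#' `min_pattern_frequency` of the pre-filter read total, are treated as
#' technical errors (incomplete bisulfite conversion, PCR or sequencing
#' errors) and removed.
#'
#' @param min_coverage minimum reads fully covering the segment (default 16).
#' @param min_pattern_reads minimum reads supporting a retained pattern
#'   (default 2).
#' @param min_pattern_frequency minimum retained pattern frequency,
#'   relative to the pre-filter total (default 1/32); frequencies exactly
#'   equal to the threshold are retained.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 16L, min_pattern_reads = 2L,
                          min_pattern_frequency = 1 / 32) {
  if (min_coverage < 1L || min_pattern_reads < 1L)
    stop("coverage and pattern-read thresholds must be positive")
  if (min_pattern_frequency <= 0 || min_pattern_frequency >= 1)
    stop("'min_pattern_frequency' must lie in (0, 1)")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_pattern_reads = as.integer(min_pattern_reads),
                 min_pattern_frequency = min_pattern_frequency),
            class = "filter_config")
}

#' Apply the error-pattern filter cascade to one segment
#'
#' Segments with fewer than `cfg$min_coverage` covering reads are flagged
#' as having insufficient coverage (see [coverage_ok()]) and returned
#' unfiltered; batch drivers drop them. Otherwise the read-count and
#' frequency thresholds are applied jointly in one pass, both against the
#' pre-filter read total `N`, and the surviving counts are returned with
#' `N` renormalized to their sum.
#'
#' @param pc a [pattern_counts()].
#' @param cfg a [filter_config()].
#' @return A `pattern_counts` of the retained patterns, with attributes
#'   `prefilter_N` (the input total) and `coverage_ok`.
#' @examples
#' pc <- pattern_counts(c(`0` = 24, `15` = 6, `3` = 1, `5` = 1))
#' apply_filters(pc, filter_config())  # keeps 24 and 6; N' = 30
#' @export
apply_filters <- function(pc, cfg = filter_config()) {
  stopifnot(inherits(pc, "pattern_counts"), inherits(cfg, "filter_config"))
  if (pc$N < cfg$min_coverage) {
    attr(pc, "prefilter_N") <- pc$N
    attr(pc, "coverage_ok") <- FALSE
    return(pc)
  }
  keep <- pc$counts >= cfg$min_pattern_reads &
    pc$counts / pc$N >= cfg$min_pattern_frequency
  out <- pattern_counts(pc$counts[keep], b = pc$b, chrom = pc$chrom,
                        positions = pc$positions)
  attr(out, "prefilter_N") <- pc$N
  attr(out, "coverage_ok") <- TRUE
  out
}

#' @rdname apply_filters
#' @export
coverage_ok <- function(pc) {
  isTRUE(attr(pc, "coverage_ok"))
}
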