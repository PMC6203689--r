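# Shared driver: index call rows by segment.
#
# Maps each call row to its CpG site rank on its chromosome and returns,
# per segment, the call rows falling on the segment's sites together with
# the within-segment slot (1..b) of each row. Row ranges are located with
# findInterval on the sorted site ranks, so the per-segment cost scales
# with the reads covering it.
segment_apply <- function(calls, sites, b = 4L, step = 1L, fun) {
  segments <- make_segments(sites, b = b, step = step)
  if (!nrow(segments)) return(list(segments = segments, results = list()))
  if (is.numeric(sites)) sites <- data.frame(chrom = "chr", pos = sites)
  results <- vector("list", nrow(segments))
  for (chr in unique(segments$chrom)) {
    pos <- sort(unique(as.integer(sites$pos[sites$chrom == chr])))
    rows <- which(calls$chrom == chr)
    gi <- match(calls$pos[rows], pos)
    rows <- rows[!is.na(gi)]
    gi <- gi[!is.na(gi)]
    o <- order(gi)
    rows <- rows[o]
    gi <- gi[o]
    segs <- which(segments$chrom == chr)
    first <- match(vapply(segments$positions[segs], `[`, 0L, 1L), pos)
    lo <- findInterval(first - 1L, gi) + 1L
    hi <- findInterval(first + b - 1L, gi)
    for (j in seq_along(segs)) {
      idx <- if (lo[j] <= hi[j]) rows[lo[j]:hi[j]] else integer(0)
      slot <- gi[seq.int(lo[j], length.out = max(0L, hi[j] - lo[j] + 1L))] -
        first[j] + 1L
      results[[segs[j]]] <- fun(calls[idx, , drop = FALSE], slot,
                                segments[segs[j], , drop = FALSE])
    }
  }
  list(segments = segments, results = results)
}

#' Per-segment methylation level and heterogeneity from bulk calls
#'
#' The main bulk pipeline: enumerates segments of `b` consecutive CpG
#' sites, tallies the methylation pattern of every read that fully covers
#' a segment, applies the error-pattern filter cascade, and computes
#' methylation level, normalized Shannon entropy and Gini index on the
#' retained reads. Segments with fewer than `cfg$min_coverage` covering
#' reads, or with no reads surviving the filters, are dropped unless
#' `keep_rejected` is set (their metric columns are then `NA`).
#'
#' @param calls call table from [read_methylation_calls()] (cells, if
#'   any, are pooled; use [gold_standard_table()] for per-cell analysis).
#' @param sites CpG site table from [enumerate_cpg_sites()], or a numeric
#'   position vector for a single chromosome.
#' @param b,step segment size and window step, see [make_segments()].
#' @param cfg a [filter_config()].
#' @param keep_rejected keep rows for segments failing the coverage or
#'   filter thresholds.
#' @return A data.frame with one row per segment: `chrom`, `start`, `end`,
#'   `cpg_positions` (comma-separated), `n_reads` (pre-filter),
#'   `n_reads_filtered`, `k_patterns` (post-filter), `meth_level`,
#'   `shannon_entropy`, `gini_index` (all post-filter), and
#'   `meth_level_prefilter` (level over all covering reads, kept for
#'   reference since the filter is aimed at heterogeneity, not level).
#' @export
segment_heterogeneity <- function(calls, sites, b = 4L, step = 1L,
                                  cfg = filter_config(),
                                  keep_rejected = FALSE) {
  run <- segment_apply(calls, sites, b = b, step = step,
                       function(sub, slot, seg) {
    counts <- tally_patterns(sub$read, slot, sub$call == "M", b)
    pattern_counts(counts, b = b, chrom = seg$chrom,
                   positions = seg$positions[[1L]])
  })
  rows <- lapply(seq_along(run$results), function(i) {
    pc <- run$results[[i]]
    seg <- run$segments[i, ]
    fpc <- apply_filters(pc, cfg)
    ok <- coverage_ok(fpc) && fpc$N >= 1L
    if (!ok && !keep_rejected) return(NULL)
    data.frame(
      chrom = seg$chrom, start = seg$start, end = seg$end,
      cpg_positions = paste(seg$positions[[1L]], collapse = ","),
      n_reads = pc$N,
      n_reads_filtered = if (coverage_ok(fpc)) fpc$N else NA_integer_,
      k_patterns = if (coverage_ok(fpc)) fpc$k else NA_integer_,
      meth_level = if (ok) methylation_level(fpc) else NA_real_,
      shannon_entropy = if (ok) shannon_entropy(fpc) else NA_real_,
      gini_index = if (ok) gini_index(fpc) else NA_real_,
      meth_level_prefilter = if (pc$N >= 1L) methylation_level(pc)
                             else NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cpg_positions = character(0),
                      n_reads = integer(0), n_reads_filtered = integer(0),
                      k_patterns = integer(0), meth_level = numeric(0),
                      shannon_entropy = numeric(0), gini_index = numeric(0),
                      meth_level_prefilter = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Pool per-cell pattern counts of one segment
#'
#' Sums pattern counts across cells, emulating an in-silico merge of
#' single-cell libraries into one bulk library for the same segment. The
#' pooled counts can then be filtered ([apply_filters()]) and scored with
#' the heterogeneity metrics.
#'
#' @param pcs a non-empty list of [pattern_counts()] for the same segment
#'   (equal `b`; equal coordinates where set).
#' @return A single pooled `pattern_counts`.
#' @export
merge_cells <- function(pcs) {
  if (!length(pcs)) stop("no pattern counts to merge")
  stopifnot(all(vapply(pcs, inherits, TRUE, "pattern_counts")))
  b <- unique(vapply(pcs, `[[`, 0L, "b"))
  if (length(b) != 1L) stop("cannot merge counts with different 'b'")
  key <- unique(vapply(pcs, function(p)
    paste(p$chrom, paste(p$positions, collapse = ",")), ""))
  if (length(key) != 1L)
    stop("cannot merge counts from different segments")
  all_counts <- unlist(unname(lapply(pcs, `[[`, "counts")))
  counts <- tapply(all_counts, names(all_counts), sum)
  pattern_counts(stats::setNames(as.integer(counts), names(counts)),
                 b = b, chrom = pcs[[1L]]$chrom,
                 positions = pcs[[1L]]$positions)
}
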