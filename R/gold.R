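#' Call the epiallele pair of one cell at one segment
#'
#' A diploid cell carries two epialleles per segment. The two most
#' frequent methylation patterns among the cell's reads (`A1`, `A2`) are
#' candidate epialleles; the ratio of their read counts separates a
#' genuinely heterozygous cell (`A1`/`A2`, ratio near 1) from a homozygous
#' one whose minor pattern stems from technical error (`A1`/`A1`, large
#' ratio). When only one pattern is observed, a pseudo second pattern with
#' read count 1 takes the place of `A2` so the ratio test still applies;
#' if that pseudo ratio stays below the cutoff the cell is called
#' indeterminate (too shallow to exclude an unseen second allele) and is
#' left out of the gold standard.
#'
#' @param pc [pattern_counts()] of one cell's reads over the segment.
#' @param ratio_cutoff frequency-ratio threshold separating heterozygous
#'   (ratio below) from homozygous (ratio at or above); default 11.5.
#' @param min_reads minimum reads before a call is attempted (default 1);
#'   shallower cells are indeterminate.
#' @param cell cell identifier carried through to the call.
#' @return An object of class `epiallele_call`: list with `cell`,
#'   `chrom`, `positions`, `a1`, `a2` (integer pattern codes; `a2` is `NA`
#'   when unobserved), `ratio`, `zygosity` (`"heterozygous"`,
#'   `"homozygous"` or `"indeterminate"`) and `n_reads`.
#' @examples
#' call_epiallele_pair(pattern_counts(c(MMMM = 10, UUUU = 10)))  # het
#' call_epiallele_pair(pattern_counts(c(MMMM = 30)))             # hom
#' @export
call_epiallele_pair <- function(pc, ratio_cutoff = 11.5, min_reads = 1L,
                                cell = NA_character_) {
  stopifnot(inherits(pc, "pattern_counts"))
  if (pc$N < 1L) stop("no covering reads (N = 0)")
  codes <- as.integer(names(pc$counts))
  o <- order(-pc$counts, codes)          # count desc, code asc on ties
  a1 <- codes[o[1L]]
  n1 <- pc$counts[o[1L]]
  if (pc$k >= 2L) {
    a2 <- codes[o[2L]]
    n2 <- pc$counts[o[2L]]
    pseudo <- FALSE
  } else {
    a2 <- NA_integer_
    n2 <- 1L                             # pseudo pattern, count 1
    pseudo <- TRUE
  }
  ratio <- as.numeric(n1) / as.numeric(n2)
  zyg <- if (pc$N < min_reads) "indeterminate"
    else if (ratio >= ratio_cutoff) "homozygous"
    else if (pseudo) "indeterminate"
    else "heterozygous"
  if (zyg != "heterozygous") a2 <- if (zyg == "homozygous") a1
                                   else NA_integer_
  structure(list(cell = cell, chrom = pc$chrom, positions = pc$positions,
                 a1 = a1, a2 = a2, ratio = ratio, zygosity = zyg,
                 n_reads = pc$N),
            class = "epiallele_call")
}

#' @export
print.epiallele_call <- function(x, ...) {
  b <- if (!is.null(x$positions)) length(x$positions)
       else max(4L, ceiling(log2(x$a1 + 1)))
  a2 <- if (is.na(x$a2)) "?" else decode_pattern(x$a2, b)
  cat(sprintf("epiallele_call  cell=%s  %s/%s  ratio=%.3g  %s  (N=%d)\n",
              x$cell, decode_pattern(x$a1, b), a2, x$ratio, x$zygosity,
              x$n_reads))
  invisible(x)
}

zygosities <- function(calls) {
  if (inherits(calls, "epiallele_call")) calls <- list(calls)
  vapply(calls, `[[`, "", "zygosity")
}

#' Fraction of heterozygous epiallele calls
#'
#' Among determinate calls (heterozygous or homozygous), the fraction
#' called heterozygous; indeterminate calls are excluded from both
#' numerator and denominator. Computed over whatever collection is passed
#' in — typically all determinate segment-by-cell calls of a cohort.
#'
#' @param calls a list of [call_epiallele_pair()] results.
#' @return A number in `[0, 1]`.
#' @export
heterozygous_fraction <- function(calls) {
  z <- zygosities(calls)
  det <- z %in% c("heterozygous", "homozygous")
  if (!any(det)) stop("no determinate epiallele calls")
  mean(z[det] == "heterozygous")
}

determinate_calls <- function(calls) {
  if (inherits(calls, "epiallele_call")) calls <- list(calls)
  calls[zygosities(calls) %in% c("heterozygous", "homozygous")]
}

#' Gold-standard heterogeneity of one segment from single-cell calls
#'
#' Pools the epialleles of all determinate cells at a segment — two per
#' cell: `A1` and `A2` for a heterozygote, `A1` twice for a homozygote —
#' and computes normalized Shannon entropy and Gini index over the
#' resulting `2 * n_cells` allele multiset (`b = 4`). This single-cell
#' quantity is the gold standard against which bulk read-level estimates
#' are calibrated. The per-cell entropy over concatenated allele pairs
#' ([cellwise_entropy()]) is reported alongside.
#'
#' @param calls list of [call_epiallele_pair()] results for one segment;
#'   indeterminate calls are dropped, at least one determinate call is
#'   required.
#' @return An object of class `gold_standard`: list with `chrom`,
#'   `positions`, `n_cells`, `n_het`, `n_hom`, `epiallele_counts` (a
#'   [pattern_counts()] with `N = 2 * n_cells`), `entropy_epiallele`,
#'   `gini_epiallele`, `entropy_cellwise`.
#' @export
gold_entropy <- function(calls) {
  det <- determinate_calls(calls)
  if (!length(det)) stop("no determinate epiallele calls for the segment")
  alleles <- unlist(lapply(det, function(x) c(x$a1, x$a2)))
  tab <- table(alleles)
  b <- length(det[[1L]]$positions)
  if (!b) b <- 4L
  pc <- pattern_counts(stats::setNames(as.integer(tab), names(tab)),
                       b = b, chrom = det[[1L]]$chrom,
                       positions = det[[1L]]$positions)
  z <- zygosities(det)
  structure(list(chrom = det[[1L]]$chrom, positions = det[[1L]]$positions,
                 n_cells = length(det),
                 n_het = sum(z == "heterozygous"),
                 n_hom = sum(z == "homozygous"),
                 epiallele_counts = pc,
                 entropy_epiallele = shannon_entropy(pc),
                 gini_epiallele = gini_index(pc),
                 entropy_cellwise = cellwise_entropy(det)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(paste0("gold_standard  %s  cells=%d (het=%d hom=%d)\n",
                     "  entropy(epiallele)=%.4f  gini=%.4f  ",
                     "entropy(cell-wise)=%.4f\n"),
              if (is.na(x$chrom)) "" else x$chrom, x$n_cells, x$n_het,
              x$n_hom, x$entropy_epiallele, x$gini_epiallele,
              x$entropy_cellwise))
  invisible(x)
}

#' Cell-to-cell entropy over concatenated epiallele pairs
#'
#' The pooled-epiallele entropy of [gold_entropy()] mixes cell-to-cell
#' heterogeneity with within-cell (allelic) heterogeneity. To isolate the
#' cell-to-cell component, each cell's two 4-site epialleles are
#' concatenated into a single 8-site pattern — ordered canonically
#' (smaller pattern code first) so that (A, B) and (B, A) coincide — and
#' normalized Shannon entropy is computed over the `n_cells` concatenated
#' patterns with `b = 8`.
#'
#' @param calls list of determinate [call_epiallele_pair()] results for
#'   one segment (indeterminate calls are dropped).
#' @return Normalized entropy in `[0, 1]`.
#' @export
cellwise_entropy <- function(calls) {
  det <- determinate_calls(calls)
  if (!length(det)) stop("no determinate epiallele calls for the segment")
  b <- length(det[[1L]]$positions)
  if (!b) b <- 4L
  code8 <- vapply(det, function(x) {
    lo <- min(x$a1, x$a2)
    hi <- max(x$a1, x$a2)
    lo + 2^b * hi
  }, 0)
  tab <- table(code8)
  pc <- pattern_counts(stats::setNames(as.integer(tab), names(tab)),
                       b = 2L * b)
  shannon_entropy(pc)
}

#' Gold-standard table across segments from single-cell call data
#'
#' Runs the single-cell gold-standard pipeline: for every segment of `b`
#' consecutive CpG sites, tallies each cell's read patterns, calls the
#' cell's epiallele pair, and summarizes determinate cells with
#' [gold_entropy()]. Segments with no determinate cell are dropped.
#'
#' @param calls call table from [read_methylation_calls()] with per-cell
#'   identifiers in the `cell` column.
#' @param sites CpG site table ([enumerate_cpg_sites()]) or numeric
#'   position vector for one chromosome.
#' @param b,step see [make_segments()].
#' @param ratio_cutoff,min_reads see [call_epiallele_pair()].
#' @return A data.frame with columns `chrom`, `start`, `end`,
#'   `cpg_positions`, `n_cells`, `n_het`, `n_hom`, `entropy_epiallele`,
#'   `gini_epiallele`, `entropy_cellwise`.
#' @export
gold_standard_table <- function(calls, sites, b = 4L, step = 1L,
                                ratio_cutoff = 11.5, min_reads = 1L) {
  run <- segment_apply(calls, sites, b = b, step = step,
                       function(sub, slot, seg) {
    rows <- lapply(split(seq_len(nrow(sub)), sub$cell), function(ix) {
      counts <- tally_patterns(sub$read[ix], slot[ix],
                               sub$call[ix] == "M", b)
      if (!sum(counts)) return(NULL)
      call_epiallele_pair(
        pattern_counts(counts, b = b, chrom = seg$chrom,
                       positions = seg$positions[[1L]]),
        ratio_cutoff = ratio_cutoff, min_reads = min_reads,
        cell = sub$cell[ix[1L]])
    })
    rows[!vapply(rows, is.null, TRUE)]
  })
  rows <- lapply(seq_along(run$results), function(i) {
    det <- determinate_calls(run$results[[i]])
    if (!length(det)) return(NULL)
    gs <- gold_entropy(det)
    seg <- run$segments[i, ]
    data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
               cpg_positions = paste(seg$positions[[1L]], collapse = ","),
               n_cells = gs$n_cells, n_het = gs$n_het, n_hom = gs$n_hom,
               entropy_epiallele = gs$entropy_epiallele,
               gini_epiallele = gs$gini_epiallele,
               entropy_cellwise = gs$entropy_cellwise)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cpg_positions = character(0),
                      n_cells = integer(0), n_het = integer(0),
                      n_hom = integer(0), entropy_epiallele = numeric(0),
                      gini_epiallele = numeric(0),
                      entropy_cellwise = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
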