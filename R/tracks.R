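#' Write and re-read the per-segment result table
#'
#' Serializes segment results as a tab-delimited table with the fixed
#' header `chrom`, `start`, `end`, `cpg_positions`, `n_reads`,
#' `n_reads_filtered`, `k_patterns`, `meth_level`, `shannon_entropy`,
#' `gini_index` (plus `meth_level_prefilter` when present). Floating
#' point columns are printed with 6 decimals; rows are sorted by
#' chromosome, start, then end. An empty result set yields a header-only
#' file.
#'
#' @param results segment table from [segment_heterogeneity()].
#' @param path output file.
#' @return `write_segment_table` returns `path` invisibly;
#'   `read_segment_table` returns the table.
#' @export
write_segment_table <- function(results, path) {
  cols <- c("chrom", "start", "end", "cpg_positions", "n_reads",
            "n_reads_filtered", "k_patterns", "meth_level",
            "shannon_entropy", "gini_index")
  if (!all(cols %in% names(results)))
    stop("missing columns: ",
         paste(setdiff(cols, names(results)), collapse = ", "))
  if ("meth_level_prefilter" %in% names(results))
    cols <- c(cols, "meth_level_prefilter")
  out <- results[cols]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  for (col in c("meth_level", "shannon_entropy", "gini_index",
                "meth_level_prefilter"))
    if (col %in% cols) out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character",
                                   cpg_positions = "character"))
}

#' Map Shannon entropy to the browser color gradient
#'
#' Linear interpolation from light blue (RGB 173,216,230) at entropy 0 —
#' lowest heterogeneity — to dark blue (RGB 0,0,139) at entropy 1,
#' highest heterogeneity. Components are rounded to the nearest integer
#' (halves up).
#'
#' @param entropy numeric vector in `[0, 1]`.
#' @return A character vector of `"r,g,b"` strings.
#' @examples
#' entropy_color(c(0, 0.5, 1))
#' @export
entropy_color <- function(entropy) {
  if (any(is.na(entropy)) || any(entropy < 0 | entropy > 1))
    stop("entropy values must lie in [0, 1]")
  light <- c(173, 216, 230)
  dark <- c(0, 0, 139)
  comp <- vapply(1:3, function(i)
    floor(light[i] + (dark[i] - light[i]) * entropy + 0.5), entropy)
  comp <- matrix(comp, ncol = 3L)
  paste(comp[, 1L], comp[, 2L], comp[, 3L], sep = ",")
}

#' Export a Shannon-entropy genome-browser track
#'
#' Writes per-segment entropy either as a 4-column bedGraph (chrom,
#' start, end, entropy) or as a BED9 track whose `itemRgb` column encodes
#' entropy on the light-blue-to-dark-blue gradient of [entropy_color()],
#' suitable for UCSC-style browsers.
#'
#' @param results segment table with `chrom`, `start`, `end`,
#'   `shannon_entropy` (0-based half-open coordinates).
#' @param path output file.
#' @param format `"bedgraph"` or `"bed9"`.
#' @return `path`, invisibly.
#' @export
write_entropy_track <- function(results, path,
                                format = c("bedgraph", "bed9")) {
  format <- match.arg(format)
  ent <- results$shannon_entropy
  if (any(is.na(ent)) || any(ent < 0 | ent > 1))
    stop("entropy values must lie in [0, 1]")
  o <- order(results$chrom, results$start, results$end)
  results <- results[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    results$chrom,
    IRanges::IRanges(start = results$start + 1L, end = results$end))
  if (format == "bedgraph") {
    gr$score <- round(results$shannon_entropy, 6)
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    rgb <- strsplit(entropy_color(results$shannon_entropy), ",")
    gr$name <- sprintf("%s:%d-%d", results$chrom, results$start,
                       results$end)
    gr$score <- as.integer(floor(results$shannon_entropy * 1000 + 0.5))
    BiocGenerics::strand(gr) <- "+"
    gr$thick <- IRanges::ranges(gr)
    gr$itemRgb <- vapply(rgb, function(x)
      grDevices::rgb(as.integer(x[1L]), as.integer(x[2L]),
                     as.integer(x[3L]), maxColorValue = 255), "")
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}
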