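#' Read gene models from a BED6 file
#'
#' Imports transcript spans (chrom, start, end, name, score, strand) and
#' returns them as a 0-based half-open gene-model table. When several
#' entries share a name (multiple transcripts of one gene), either the
#' longest span is kept or the spans are collapsed to their union.
#'
#' @param path BED6 file.
#' @param collapse how to resolve multiple entries per gene name:
#'   `"longest"` (default) or `"union"`.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_models <- function(path, collapse = c("longest", "union")) {
  collapse <- match.arg(collapse)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    gene = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  if (any(df$strand == "*"))
    stop("BED6 gene models require an explicit strand")
  if (anyDuplicated(df$gene)) {
    parts <- split(df, df$gene)
    df <- do.call(rbind, lapply(parts, function(d) {
      if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L)
        stop("gene '", d$gene[1L], "' maps to multiple chromosomes/strands")
      if (collapse == "longest") d[which.max(d$end - d$start), ]
      else data.frame(gene = d$gene[1L], chrom = d$chrom[1L],
                      start = min(d$start), end = max(d$end),
                      strand = d$strand[1L])
    }))
    rownames(df) <- NULL
  }
  df
}

region_names <- c("Upstream1000", "Upstream500", "GeneBody",
                  "Downstream500", "Downstream1000")

#' Derive the five standard regions of a gene
#'
#' For each gene the five regions are: 1000 bp and 500 bp upstream of the
#' transcription start site (TSS), the gene body (TSS to transcription
#' end site, TES), and 500 bp and 1000 bp downstream of the TES. The two
#' upstream (and downstream) windows are nested, the longer containing
#' the shorter. Regions are strand-aware: for a minus-strand gene the TSS
#' is the higher transcript coordinate and upstream extends to higher
#' coordinates. Windows are clipped at position 0 and, when
#' `chrom_lengths` is supplied, at the chromosome end.
#'
#' @param genes gene-model table as from [read_gene_models()] (columns
#'   `gene`, `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param chrom_lengths optional named integer vector of chromosome
#'   lengths for right-side clipping.
#' @return A data.frame with columns `gene`, `region`, `chrom`, `start`,
#'   `end`, `strand` — five rows per gene (zero-width windows after
#'   clipping are kept with `start == end`).
#' @examples
#' derive_regions(data.frame(gene = "g", chrom = "chr1",
#'                           start = 10000, end = 12000, strand = "+"))
#' @export
derive_regions <- function(genes, chrom_lengths = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(genes$start < genes$end),
            all(genes$strand %in% c("+", "-")))
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      win <- rbind(c(g$start - 1000, g$start), c(g$start - 500, g$start),
                   c(g$start, g$end),
                   c(g$end, g$end + 500), c(g$end, g$end + 1000))
    } else {
      win <- rbind(c(g$end, g$end + 1000), c(g$end, g$end + 500),
                   c(g$start, g$end),
                   c(g$start - 500, g$start), c(g$start - 1000, g$start))
    }
    data.frame(gene = g$gene, region = region_names, chrom = g$chrom,
               start = win[, 1L], end = win[, 2L], strand = g$strand)
  }))
  out$start <- pmax(out$start, 0)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[out$chrom]
    if (anyNA(len)) stop("missing chromosome length for some regions")
    out$end <- pmin(out$end, len)
    out$start <- pmin(out$start, out$end)
  }
  out$end <- pmax(out$end, out$start)
  rownames(out) <- NULL
  out
}

#' Aggregate segment-level results over gene regions
#'
#' A segment contributes to a region iff its interval is fully contained
#' in the region (straddling segments are excluded, so no segment is
#' counted fractionally). Region-level methylation level and Shannon
#' entropy are unweighted means over the contributing segments, with
#' bootstrap standard errors ([bootstrap_se()]).
#'
#' @param segments segment result table from [segment_heterogeneity()]
#'   (columns `chrom`, `start`, `end`, `meth_level`, `shannon_entropy`).
#'   Duplicated segments are rejected.
#' @param regions region table from [derive_regions()].
#' @param n_boot,seed bootstrap replicates and RNG seed for the standard
#'   errors.
#' @return A data.frame with one row per region: `gene`, `region`,
#'   `chrom`, `start`, `end`, `n_segments`, `mean_meth_level`,
#'   `se_meth_level`, `mean_entropy`, `se_entropy`, `seed`. Regions with
#'   no contributing segment have `NA` means and SEs.
#' @export
aggregate_regions <- function(segments, regions, n_boot = 1000L,
                              seed = 1L) {
  key <- paste(segments$chrom, segments$start, segments$end)
  if (anyDuplicated(key))
    stop("duplicated segments in input: ",
         key[duplicated(key)][1L])
  segments <- segments[!is.na(segments$shannon_entropy), , drop = FALSE]
  out <- regions
  out$n_segments <- 0L
  out$mean_meth_level <- NA_real_
  out$se_meth_level <- NA_real_
  out$mean_entropy <- NA_real_
  out$se_entropy <- NA_real_
  out$seed <- as.integer(seed)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- segments$chrom == r$chrom & segments$start >= r$start &
      segments$end <= r$end
    n <- sum(hit)
    out$n_segments[i] <- n
    if (!n) next
    lev <- segments$meth_level[hit]
    ent <- segments$shannon_entropy[hit]
    out$mean_meth_level[i] <- mean(lev)
    out$mean_entropy[i] <- mean(ent)
    out$se_meth_level[i] <- bootstrap_se(lev, n_boot, seed)$standard_error
    out$se_entropy[i] <- bootstrap_se(ent, n_boot, seed)$standard_error
  }
  rownames(out) <- NULL
  out
}
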