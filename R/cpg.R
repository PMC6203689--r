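#' Enumerate CpG sites in a genome
#'
#' Scans each chromosome for `CG` dinucleotides and records the 0-based
#' forward-strand position of the C. CpG methylation is symmetric across
#' strands, so each dinucleotide yields exactly one site regardless of
#' which strand a read maps to. Ambiguity codes (`N` etc.) never form a
#' site.
#'
#' @param genome a named `character` vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @return A data.frame with columns `chrom` and `pos` (0-based position
#'   of the C), sorted by chromosome then position.
#' @examples
#' enumerate_cpg_sites(c(chr1 = "ACGTCGCG"))  # positions 1, 4, 6
#' @export
enumerate_cpg_sites <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("'genome' must be sequences, a DNAStringSet or a FASTA path")
  nm <- names(genome)
  if (is.null(nm)) stop("chromosome sequences must be named")
  # FASTA headers may carry descriptions; keep the first word
  nm <- vapply(strsplit(nm, "\\s+"), `[`, "", 1L)
  hits <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern("CG", genome[[i]], fixed = TRUE)
    data.frame(chrom = rep(nm[i], length(m)),
               pos = BiocGenerics::start(m) - 1L)
  })
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Build segments of consecutive CpG sites
#'
#' Slides a window of `b` consecutive CpG sites along the genome-wide CpG
#' ordering of each chromosome, advancing by `step` sites. The default
#' (`b = 4`, `step = 1`) enumerates every segment of 4 consecutive CpG
#' sites, with successive segments overlapping by 3 sites; `step = b`
#' gives the non-overlapping tiling.
#'
#' @param sites CpG site table from [enumerate_cpg_sites()] (columns
#'   `chrom`, `pos`), or a bare numeric vector of positions for a single
#'   chromosome.
#' @param b sites per segment (>= 2).
#' @param step number of sites to advance between successive segments.
#' @return A data.frame with one row per segment: `chrom`, `start`, `end`
#'   (0-based half-open interval from the first C to the last G), and
#'   `positions` (list column of the `b` site positions).
#' @examples
#' make_segments(c(1, 4, 6, 9, 15))  # two overlapping 4-site segments
#' @export
make_segments <- function(sites, b = 4L, step = 1L) {
  if (b < 2L) stop("'b' must be at least 2")
  if (step < 1L) stop("'step' must be at least 1")
  if (is.numeric(sites)) sites <- data.frame(chrom = "chr", pos = sites)
  out <- lapply(split(sites$pos, sites$chrom), function(pos) {
    pos <- sort(unique(as.integer(pos)))
    if (length(pos) < b) return(NULL)
    first <- seq.int(1L, length(pos) - b + 1L, by = step)
    list(start = pos[first], end = pos[first + b - 1L] + 2L,
         positions = lapply(first, function(i) pos[i:(i + b - 1L)]))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  seg <- data.frame(
    chrom = rep(names(out), vapply(out, function(x) length(x$start), 0L)),
    start = unlist(lapply(out, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(out, `[[`, "end"), use.names = FALSE))
  seg$positions <- unname(do.call(c, lapply(out, `[[`, "positions")))
  rownames(seg) <- NULL
  seg
}
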