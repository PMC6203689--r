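#' Configuration for the diploid epiallele cohort simulator
#'
#' Describes a simulated cohort of diploid cells: each segment carries a
#' small pool of epiallele methylation patterns with population
#' frequencies, each cell independently draws two alleles from the pool,
#' and reads are drawn from the two alleles with technical errors
#' injected per site. The defaults describe a 20-cell cohort resembling
#' serum-cultured embryonic stem cells profiled by single-cell BS-seq:
#' per-segment pools of 1-3 patterns with symmetric-Dirichlet(2)
#' frequencies (a mix of clonal and polymorphic segments), 24 reads per
#' cell per segment, and small error rates for bisulfite non-conversion
#' (an unmethylated site read as methylated), over-conversion (a
#' methylated site read as unmethylated) and sequencing error (either
#' direction, applied after conversion errors).
#'
#' @param n_segments number of simulated segments.
#' @param n_cells cells per cohort (default 20).
#' @param b CpG sites per segment (default 4).
#' @param coverage reads per cell per segment: the fixed count
#'   (`coverage_model = "fixed"`, default) or the Poisson mean.
#' @param coverage_model `"fixed"` or `"poisson"`.
#' @param non_conversion,over_conversion,seq_error per-site error
#'   probabilities, each in `[0, 0.5)`.
#' @param pool_sizes candidate numbers of distinct epialleles per
#'   segment; one is drawn uniformly per segment.
#' @param pool_alpha symmetric Dirichlet concentration for pool
#'   frequencies.
#' @param pools optional explicit per-segment pools overriding the random
#'   ones: a list of data.frames with columns `pattern` (integer code or
#'   `M`/`U` string) and `freq` (summing to 1 per segment).
#' @param pcr_duplicates integer read multiplier (1 = no duplication;
#'   duplicate removal is an upstream concern in real pipelines).
#' @param seed RNG seed; the whole cohort is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_segments = 200L, n_cells = 20L, b = 4L,
                       coverage = 24, coverage_model = c("fixed",
                                                         "poisson"),
                       non_conversion = 0.005, over_conversion = 0.005,
                       seq_error = 0.001, pool_sizes = 1:3,
                       pool_alpha = 2, pools = NULL,
                       pcr_duplicates = 1L, seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  chk <- function(ok, field)
    if (!ok) stop("invalid simulator configuration: '", field, "'")
  chk(n_segments >= 1L, "n_segments")
  chk(n_cells >= 1L, "n_cells")
  chk(b >= 2L, "b")
  chk(coverage >= 0, "coverage")
  for (f in c("non_conversion", "over_conversion", "seq_error")) {
    v <- get(f)
    chk(is.numeric(v) && v >= 0 && v < 0.5, f)
  }
  chk(all(pool_sizes >= 1L) && all(pool_sizes <= 2^b), "pool_sizes")
  chk(pool_alpha > 0, "pool_alpha")
  chk(pcr_duplicates >= 1L, "pcr_duplicates")
  if (!is.null(pools)) {
    chk(length(pools) == n_segments, "pools")
    for (p in pools)
      chk(is.data.frame(p) && all(c("pattern", "freq") %in% names(p)) &&
            abs(sum(p$freq) - 1) < 1e-8 && all(p$freq > 0), "pools")
  }
  structure(list(n_segments = as.integer(n_segments),
                 n_cells = as.integer(n_cells), b = as.integer(b),
                 coverage = coverage, coverage_model = coverage_model,
                 non_conversion = non_conversion,
                 over_conversion = over_conversion, seq_error = seq_error,
                 pool_sizes = as.integer(pool_sizes),
                 pool_alpha = pool_alpha, pools = pools,
                 pcr_duplicates = as.integer(pcr_duplicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# inject per-site errors into integer pattern codes
inject_errors <- function(codes, b, nc, oc, se) {
  n <- length(codes)
  if (!n) return(codes)
  bits <- matrix(0L, n, b)
  for (j in seq_len(b)) bits[, j] <- bitwAnd(codes %/% 2L^(j - 1L), 1L)
  flip1 <- (bits == 1L & matrix(stats::runif(n * b), n, b) < oc) |
    (bits == 0L & matrix(stats::runif(n * b), n, b) < nc)
  bits <- (bits + flip1) %% 2L
  flip2 <- matrix(stats::runif(n * b), n, b) < se
  bits <- (bits + flip2) %% 2L
  as.integer(bits %*% 2L^(seq_len(b) - 1L))
}

#' Simulate a single-cell and bulk BS-seq cohort with known truth
#'
#' Generates read-level methylation patterns for every cell and segment
#' of a [sim_config()]. Per segment, each cell draws two epialleles from
#' the segment's pool (independently, emulating a diploid genotype);
#' each read picks one of the cell's two alleles uniformly and is then
#' corrupted site-by-site with the configured error rates (bisulfite
#' non-conversion on unmethylated sites, over-conversion on methylated
#' sites, then sequencing error on either). The bulk sample is the union
#' of all cells' reads with cell identity erased. Segments are laid out
#' on one synthetic chromosome, well separated so 4-site windows never
#' span two simulated segments.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `meth_cohort`: list with `config`, `sites`
#'   (CpG site table usable by the pipeline functions), `segments`
#'   (chrom/start/end/positions), `truth` (per segment: `pool`,
#'   realized `alleles` matrix of `n_cells` rows by 2, and
#'   `entropy_true` — see [true_population_entropy()]) and `reads`
#'   (data.frame: `segment`, `cell`, `read`, `code` before and after
#'   error injection, columns `code_true` and `code`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    b <- cfg$b
    gap <- 200L
    offs <- as.integer(seq(0L, by = 10L, length.out = b))
    seg_start <- (seq_len(cfg$n_segments) - 1L) * gap
    positions <- lapply(seg_start, function(s) s + offs)
    sites <- data.frame(chrom = "chrS",
                        pos = unlist(positions, use.names = FALSE))
    segments <- data.frame(chrom = "chrS", start = seg_start,
                           end = seg_start + offs[b] + 2L)
    segments$positions <- positions
    truth <- vector("list", cfg$n_segments)
    reads <- vector("list", cfg$n_segments)
    cells <- sprintf("cell%02d", seq_len(cfg$n_cells))
    for (s in seq_len(cfg$n_segments)) {
      if (is.null(cfg$pools)) {
        npat <- if (length(cfg$pool_sizes) > 1L)
          sample(cfg$pool_sizes, 1L) else cfg$pool_sizes
        pats <- sample.int(2L^b, npat) - 1L
        w <- stats::rgamma(npat, shape = cfg$pool_alpha)
        pool <- data.frame(pattern = pats, freq = w / sum(w))
      } else {
        pool <- cfg$pools[[s]]
        pat <- pool$pattern
        if (is.character(pat))
          pat <- vapply(pat, encode_pattern, integer(1))
        pool <- data.frame(pattern = as.integer(pat), freq = pool$freq)
      }
      alleles <- matrix(pool$pattern[sample.int(nrow(pool),
                                                2L * cfg$n_cells,
                                                replace = TRUE,
                                                prob = pool$freq)],
                        ncol = 2L)
      cov <- if (cfg$coverage_model == "fixed")
        rep(as.integer(round(cfg$coverage)), cfg$n_cells)
      else stats::rpois(cfg$n_cells, cfg$coverage)
      cell_of <- rep(seq_len(cfg$n_cells), cov)
      pick <- sample(c(1L, 2L), length(cell_of), replace = TRUE)
      code_true <- alleles[cbind(cell_of, pick)]
      if (cfg$pcr_duplicates > 1L) {
        cell_of <- rep(cell_of, cfg$pcr_duplicates)
        code_true <- rep(code_true, cfg$pcr_duplicates)
      }
      code <- inject_errors(code_true, b, cfg$non_conversion,
                            cfg$over_conversion, cfg$seq_error)
      truth[[s]] <- list(
        pool = pool, alleles = alleles,
        entropy_true = entropy_of_codes(as.vector(alleles), b))
      reads[[s]] <- if (length(cell_of)) data.frame(
        segment = s, cell = cells[cell_of],
        read = sprintf("s%d_r%d", s, seq_along(cell_of)),
        code_true = code_true, code = code) else NULL
    }
    structure(list(config = cfg, sites = sites, segments = segments,
                   truth = truth,
                   reads = do.call(rbind, reads[!vapply(reads, is.null,
                                                        TRUE)])),
              class = "meth_cohort")
  })
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(paste0("meth_cohort: %d segments x %d cells, b=%d, ",
                     "%d reads (seed %d)\n"),
              x$config$n_segments, x$config$n_cells, x$config$b,
              nrow(x$reads), x$config$seed))
  invisible(x)
}

#' True epiallele-population entropy of a simulated segment
#'
#' Normalized Shannon entropy of the realized allele multiset of one
#' segment — the `2 * n_cells` epialleles actually carried by the
#' simulated cells, before any reads or errors. This is the quantity the
#' estimation pipeline should recover from (filtered) bulk reads.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param segment segment index, or `NULL` for all segments.
#' @return Numeric vector of entropies in `[0, 1]`.
#' @export
true_population_entropy <- function(cohort, segment = NULL) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (is.null(segment)) segment <- seq_along(cohort$truth)
  vapply(cohort$truth[segment], `[[`, 0, "entropy_true")
}

#' Extract call tables or pattern counts from a simulated cohort
#'
#' `cohort_calls` expands the simulated reads into the per-site call
#' table consumed by [segment_heterogeneity()] and
#' [gold_standard_table()]; with `bulk = TRUE` cell identities are
#' erased. `cohort_pattern_counts` returns the [pattern_counts()] of one
#' segment directly (per cell, or pooled), bypassing the parser.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param bulk erase cell identities (bulk mode).
#' @param segments subset of segment indices (default: all).
#' @return `cohort_calls`: a data.frame with columns `read`, `cell`,
#'   `chrom`, `pos`, `call`. `cohort_pattern_counts`: a list of
#'   `pattern_counts` per cell, or a single pooled one.
#' @export
cohort_calls <- function(cohort, bulk = FALSE, segments = NULL) {
  stopifnot(inherits(cohort, "meth_cohort"))
  rd <- cohort$reads
  if (!is.null(segments)) rd <- rd[rd$segment %in% segments, ,
                                   drop = FALSE]
  b <- cohort$config$b
  n <- nrow(rd)
  pos <- matrix(unlist(cohort$segments$positions[rd$segment],
                       use.names = FALSE),
                ncol = b, byrow = TRUE)
  bits <- vapply(seq_len(b), function(j)
    bitwAnd(rd$code %/% 2L^(j - 1L), 1L), integer(n))
  data.frame(read = rep(rd$read, each = b),
             cell = if (bulk) "bulk" else rep(rd$cell, each = b),
             chrom = "chrS",
             pos = as.integer(t(pos)),
             call = ifelse(as.vector(t(bits)) == 1L, "M", "U"))
}

#' @rdname cohort_calls
#' @param segment one segment index.
#' @param pooled sum counts across cells instead of listing per cell.
#' @export
cohort_pattern_counts <- function(cohort, segment, pooled = FALSE) {
  stopifnot(inherits(cohort, "meth_cohort"))
  rd <- cohort$reads[cohort$reads$segment == segment, , drop = FALSE]
  b <- cohort$config$b
  seg <- cohort$segments[segment, ]
  make_pc <- function(codes) {
    tab <- table(codes)
    pattern_counts(stats::setNames(as.integer(tab), names(tab)), b = b,
                   chrom = seg$chrom, positions = seg$positions[[1L]])
  }
  if (pooled) return(make_pc(rd$code))
  lapply(split(rd$code, rd$cell), make_pc)
}

#' Write a simulated cohort to call and truth files
#'
#' Emits one `simple_tsv` call file per cell (`cell01.tsv`, ...), a
#' pooled `bulk.tsv` with cell identities erased, and two truth tables:
#' `truth_segments.tsv` (segment coordinates, pool patterns and
#' frequencies, realized-population entropy) and `truth_alleles.tsv`
#' (per cell and segment, the two carried epialleles). All files are
#' plain text; patterns are written as `M`/`U` strings.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- cohort_calls(cohort)
  for (cell in unique(calls$cell)) {
    sub <- calls[calls$cell == cell, , drop = FALSE]
    utils::write.table(sub[c("read", "cell", "chrom", "pos", "call")],
                       file.path(dir, paste0(cell, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  calls$cell <- "bulk"
  utils::write.table(calls[c("read", "cell", "chrom", "pos", "call")],
                     file.path(dir, "bulk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  b <- cohort$config$b
  dec <- function(code) vapply(code, decode_pattern, "", b = b)
  segs <- cohort$segments
  truth_seg <- data.frame(
    segment = seq_len(nrow(segs)), chrom = segs$chrom,
    start = segs$start, end = segs$end,
    cpg_positions = vapply(segs$positions, paste, "", collapse = ","),
    pool_patterns = vapply(cohort$truth, function(t)
      paste(dec(t$pool$pattern), collapse = ","), ""),
    pool_freqs = vapply(cohort$truth, function(t)
      paste(sprintf("%.6f", t$pool$freq), collapse = ","), ""),
    entropy_true = sprintf("%.6f", true_population_entropy(cohort)))
  utils::write.table(truth_seg, file.path(dir, "truth_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  al <- do.call(rbind, lapply(seq_along(cohort$truth), function(s)
    data.frame(segment = s,
               cell = sprintf("cell%02d", seq_len(cohort$config$n_cells)),
               a1 = dec(cohort$truth[[s]]$alleles[, 1L]),
               a2 = dec(cohort$truth[[s]]$alleles[, 2L]))))
  utils::write.table(al, file.path(dir, "truth_alleles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
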