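test_that("CpG sites are enumerated at forward-strand C positions", {
  expect_identical(enumerate_cpg_sites(c(chr1 = "ACGTCGCG"))$pos,
                   c(1L, 4L, 6L))
  expect_identical(nrow(enumerate_cpg_sites(c(chr1 = "AAAA"))), 0L)
  expect_identical(enumerate_cpg_sites(c(chr1 = "CGCGCG"))$pos,
                   c(0L, 2L, 4L))
  # case-insensitive; N never forms a site
  expect_identical(enumerate_cpg_sites(c(chr1 = "acgtNCgCN"))$pos,
                   c(1L, 5L))
  two <- enumerate_cpg_sites(c(chr2 = "TTCGA", chr1 = "CGCG"))
  expect_identical(two$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(two$pos, c(0L, 2L, 2L))
})

test_that("FASTA input yields the same sites as in-memory sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 test sequence", "ACGTCGCG"), fa)
  expect_identical(enumerate_cpg_sites(fa)$pos, c(1L, 4L, 6L))
})

test_that("segments are sliding windows over consecutive CpG sites", {
  seg <- make_segments(c(1, 4, 6, 9, 15))
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$positions, list(c(1L, 4L, 6L, 9L),
                                       c(4L, 6L, 9L, 15L)))
  expect_identical(seg$start, c(1L, 4L))
  expect_identical(seg$end, c(11L, 17L))   # last C + 2
  expect_identical(nrow(make_segments(c(1, 4, 6))), 0L)
  expect_identical(nrow(make_segments(c(1, 4, 6, 9))), 1L)
  expect_identical(nrow(make_segments(c(1, 4, 6, 9, 15), step = 4)), 1L)
  expect_error(make_segments(1:10, b = 1), "at least 2")
  # windows never span chromosomes
  sites <- data.frame(chrom = c("c1", "c1", "c2", "c2", "c2", "c2"),
                      pos = c(1, 3, 1, 3, 5, 7))
  expect_identical(make_segments(sites)$chrom, "c2")
})

test_that("bismark extractor lines convert coordinates and collapse
           strands", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("r1 + chr1 2 Z",
               "r2 - chr1 3 z",
               "r3 + chr1 9 x",      # non-CpG context: ignored
               "r3 + chr1 2 z"), f)
  calls <- read_methylation_calls(f, "bismark_extractor", cell = "c7")
  expect_identical(calls$pos, c(1L, 1L, 1L))
  expect_identical(calls$call, c("M", "U", "U"))
  expect_identical(calls$read, c("r1", "r2", "r3"))
  expect_identical(unique(calls$cell), "c7")

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_identical(nrow(read_methylation_calls(empty,
                                               "bismark_extractor")), 0L)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("r1 + chr1 2 Z", "r2 + chr1 5 Q"), bad)
  expect_error(read_methylation_calls(bad, "bismark_extractor"),
               "unknown call letter 'Q' at line 2")
  short <- withr::local_tempfile(fileext = ".txt")
  writeLines("r1 + chr1", short)
  expect_error(read_methylation_calls(short, "bismark_extractor"),
               "line 1")
  expect_error(read_methylation_calls(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("simple_tsv lines parse as 0-based forward-strand calls", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tcellA\tchr1\t1\tM", "r1\tcellA\tchr1\t4\tU"), f)
  calls <- read_methylation_calls(f, "simple_tsv")
  expect_identical(calls$pos, c(1L, 4L))
  expect_identical(calls$cell, c("cellA", "cellA"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("r1\tcellA\tchr1\t1\tZ", bad)
  expect_error(read_methylation_calls(bad, "simple_tsv"),
               "unknown call letter")
})

test_that("a read contributes a pattern only with unambiguous calls at
           every segment site", {
  seg <- c(1, 4, 6, 9)
  full <- do.call(rbind, lapply(c("a", "b", "c"), function(r)
    data.frame(read = r, cell = "bulk", chrom = "chr1", pos = seg,
               call = "M")))
  pc <- collect_patterns(full, seg, chrom = "chr1")
  expect_identical(unname(pc$counts[as.character(encode_pattern("MMMM"))]),
                   3L)
  expect_identical(pc$N, 3L)

  partial <- data.frame(read = "p", cell = "bulk", chrom = "chr1",
                        pos = seg[1:3], call = "M")
  expect_identical(collect_patterns(rbind(full, partial), seg,
                                    chrom = "chr1")$N, 3L)

  mixed <- rbind(full,
                 data.frame(read = "d", cell = "bulk", chrom = "chr1",
                            pos = seg, call = c("M", "U", "U", "M")))
  pc2 <- collect_patterns(mixed, seg, chrom = "chr1")
  expect_identical(pc2$N, 4L)
  expect_identical(unname(pc2$counts[as.character(encode_pattern("MUUM"))]),
                   1L)

  # conflicting duplicate call at one site excludes the read
  conflict <- rbind(full,
                    data.frame(read = "a", cell = "bulk", chrom = "chr1",
                               pos = 4, call = "U"))
  expect_identical(collect_patterns(conflict, seg, chrom = "chr1")$N, 2L)
  # consistent duplicate call is harmless
  dup <- rbind(full,
               data.frame(read = "a", cell = "bulk", chrom = "chr1",
                          pos = 4, call = "M"))
  expect_identical(collect_patterns(dup, seg, chrom = "chr1")$N, 3L)
})

test_that("pattern collection is independent of read order", {
  set.seed(21)
  seg <- c(10, 12, 20, 31)
  calls <- do.call(rbind, lapply(1:15, function(i)
    data.frame(read = paste0("r", i), cell = "bulk", chrom = "chr1",
               pos = seg,
               call = sample(c("M", "U"), 4, replace = TRUE))))
  pc1 <- collect_patterns(calls, seg, chrom = "chr1")
  pc2 <- collect_patterns(calls[sample.int(nrow(calls)), ], seg,
                          chrom = "chr1")
  expect_identical(pc1$counts, pc2$counts)
})

test_that("filter cascade applies coverage, read-count and frequency
           rules with pre-filter denominators", {
  cfg <- filter_config()
  pc <- pattern_counts(c(`0` = 24, `15` = 6, `3` = 1, `5` = 1))
  f <- apply_filters(pc, cfg)
  expect_true(coverage_ok(f))
  expect_identical(f$N, 30L)
  expect_identical(sort(as.integer(names(f$counts))), c(0L, 15L))
  expect_identical(attr(f, "prefilter_N"), 32L)

  low <- apply_filters(pattern_counts(c(`0` = 15)), cfg)
  expect_false(coverage_ok(low))

  # frequency exactly 1/32 is retained (strictly-less-than removal)
  edge <- apply_filters(pattern_counts(c(`0` = 62, `1` = 2)), cfg)
  expect_identical(edge$N, 64L)
  expect_identical(edge$k, 2L)
  # one read below the boundary is removed
  below <- apply_filters(pattern_counts(c(`0` = 63, `1` = 2)), cfg)
  expect_identical(below$k, 1L)
})

test_that("filtering never grows the count multiset", {
  set.seed(22)
  for (rep in 1:30) {
    pc <- random_pc(b = 4, max_patterns = 12, max_total = 60)
    f <- apply_filters(pc, filter_config(min_coverage = 1))
    expect_lte(f$N, pc$N)
    expect_lte(f$k, pc$k)
    expect_true(all(names(f$counts) %in% names(pc$counts)))
    expect_true(all(f$counts <= pc$counts[names(f$counts)]))
  }
})

test_that("pipeline output matches a brute-force tally on a small
           fixture", {
  set.seed(23)
  seg <- c(5, 9, 14, 22)
  patterns <- c("MMMM", "MMMM", "MMMM", "MMMM", "MMMM", "MMMM", "MMMM",
                "MMMM", "UUUU", "UUUU", "UUUU", "UUUU", "UUUU", "UUUU",
                "MUMU", "MUMU", "MMMU", "UMMM", "UUUM", "MUUU")
  calls <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    st <- strsplit(patterns[i], "")[[1L]]
    data.frame(read = paste0("r", i), cell = "bulk", chrom = "chr1",
               pos = seg, call = st)
  }))
  pc <- collect_patterns(calls, seg, chrom = "chr1")
  f <- apply_filters(pc, filter_config(min_coverage = 16))
  # brute force from the raw lines: tally full reads, filter by the rules
  tallied <- table(patterns)
  expect_identical(pc$N, length(patterns))
  expect_identical(sort(unname(pc$counts)), sort(unname(as.integer(tallied))))
  keep <- tallied[tallied >= 2 & tallied / length(patterns) >= 1 / 32]
  expect_identical(f$N, sum(as.integer(keep)))
  expect_identical(f$k, length(keep))
  got <- stats::setNames(unname(f$counts),
                         vapply(as.integer(names(f$counts)),
                                decode_pattern, "", b = 4))
  expect_identical(got[sort(names(got))],
                   stats::setNames(as.integer(keep),
                                   names(keep))[sort(names(keep))])
})
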