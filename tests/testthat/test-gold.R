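test_that("epiallele pairs follow the top-two frequency-ratio rule", {
  het <- call_epiallele_pair(pattern_counts(c(`0` = 10, `15` = 10)))
  expect_identical(het$zygosity, "heterozygous")
  expect_identical(het$ratio, 1)
  expect_identical(sort(c(het$a1, het$a2)), c(0L, 15L))

  # single observed pattern: pseudo second pattern with count 1
  hom <- call_epiallele_pair(pattern_counts(c(`3` = 30)))
  expect_identical(hom$zygosity, "homozygous")
  expect_identical(hom$ratio, 30)
  expect_identical(hom$a2, hom$a1)

  # ratio exactly at the cutoff is homozygous
  edge <- call_epiallele_pair(pattern_counts(c(`3` = 23, `7` = 2)))
  expect_identical(edge$ratio, 11.5)
  expect_identical(edge$zygosity, "homozygous")
  just_below <- call_epiallele_pair(pattern_counts(c(`3` = 22, `7` = 2)))
  expect_identical(just_below$zygosity, "heterozygous")

  # a shallow pure pattern cannot exclude an unseen second allele
  shallow <- call_epiallele_pair(pattern_counts(c(`3` = 5)))
  expect_identical(shallow$zygosity, "indeterminate")
  expect_true(is.na(shallow$a2))

  expect_error(call_epiallele_pair(pattern_counts(integer(0))),
               "no covering reads")
})

test_that("ties in the top-two ranking break by canonical encoding", {
  tie <- call_epiallele_pair(pattern_counts(c(`9` = 7, `2` = 7, `4` = 7)))
  expect_identical(tie$a1, 2L)
  expect_identical(tie$a2, 4L)
})

test_that("heterozygous fraction excludes indeterminate calls", {
  mk <- function(zyg) structure(list(zygosity = zyg),
                                class = "epiallele_call")
  expect_equal(heterozygous_fraction(lapply(
    c("heterozygous", "heterozygous", "homozygous", "homozygous"), mk)),
    0.5)
  expect_equal(heterozygous_fraction(lapply(rep("homozygous", 3), mk)), 0)
  expect_equal(heterozygous_fraction(lapply(
    c(rep("heterozygous", 3), "homozygous", rep("indeterminate", 2)),
    mk)), 0.75)
  expect_error(heterozygous_fraction(lapply(rep("indeterminate", 2), mk)),
               "no determinate")
})

test_that("gold-standard entropy pools two epialleles per determinate
           cell", {
  cellpc <- function(counts) pattern_counts(counts,
                                            positions = c(1, 3, 7, 9))
  hom20 <- lapply(1:20, function(i)
    call_epiallele_pair(cellpc(c(`5` = 30))))
  gs <- gold_entropy(hom20)
  expect_identical(gs$n_cells, 20L)
  expect_identical(gs$epiallele_counts$N, 40L)
  expect_identical(gs$entropy_epiallele, 0)
  expect_identical(gs$entropy_cellwise, 0)

  two <- list(call_epiallele_pair(cellpc(c(`0` = 30))),
              call_epiallele_pair(cellpc(c(`15` = 30))))
  gs2 <- gold_entropy(two)
  expect_identical(unname(gs2$epiallele_counts$counts), c(2L, 2L))
  expect_equal(gs2$entropy_epiallele, 0.25)
  expect_equal(gs2$entropy_cellwise, 2 / 16)  # two equal categories, b=8

  one_het <- gold_entropy(list(
    call_epiallele_pair(cellpc(c(`0` = 10, `15` = 10)))))
  expect_equal(one_het$entropy_epiallele, 0.25)
  expect_identical(one_het$entropy_cellwise, 0)

  expect_error(gold_entropy(list()), "no determinate")
})

test_that("cell-wise entropy canonicalizes the concatenation order", {
  ab <- structure(list(zygosity = "heterozygous", a1 = 3L, a2 = 12L,
                       positions = c(1, 3, 5, 7)),
                  class = "epiallele_call")
  ba <- structure(list(zygosity = "heterozygous", a1 = 12L, a2 = 3L,
                       positions = c(1, 3, 5, 7)),
                  class = "epiallele_call")
  expect_identical(cellwise_entropy(list(ab, ab)), 0)
  expect_identical(cellwise_entropy(list(ab, ba)), 0)
  expect_equal(cellwise_entropy(list(ab, structure(
    list(zygosity = "homozygous", a1 = 3L, a2 = 3L,
         positions = c(1, 3, 5, 7)), class = "epiallele_call"))),
    1 / 8 * log2(2))
})

test_that("gold-standard summaries are invariant to cell order", {
  set.seed(31)
  calls <- lapply(1:12, function(i) {
    k <- sample(1:2, 1)
    counts <- stats::setNames(rep(15L, k), sample(0:15, k))
    call_epiallele_pair(pattern_counts(counts, positions = c(0, 2, 4, 6)),
                        cell = paste0("c", i))
  })
  a <- gold_entropy(calls)
  b <- gold_entropy(rev(calls))
  expect_equal(a$entropy_epiallele, b$entropy_epiallele)
  expect_equal(a$entropy_cellwise, b$entropy_cellwise)
  expect_equal(a$gini_epiallele, b$gini_epiallele)
})

test_that("merging per-cell counts sums pattern-wise", {
  pos <- c(0, 2, 4, 6)
  a <- pattern_counts(c(`3` = 3), positions = pos, chrom = "chr1")
  b <- pattern_counts(c(`3` = 2, `5` = 1), positions = pos, chrom = "chr1")
  m <- merge_cells(list(a, b))
  expect_identical(m$N, 6L)
  expect_identical(unname(m$counts[c("3", "5")]), c(5L, 1L))
  expect_identical(merge_cells(list(a))$counts, a$counts)
  expect_error(merge_cells(list()), "no pattern counts")
  other <- pattern_counts(c(`3` = 2), positions = pos + 10, chrom = "chr1")
  expect_error(merge_cells(list(a, other)), "different segments")
})
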