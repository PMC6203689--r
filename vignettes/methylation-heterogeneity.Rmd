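---
title: "Estimating cell-to-cell DNA methylation heterogeneity from read-level BS-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-to-cell DNA methylation heterogeneity from read-level BS-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methentropy)
```

## The model

A bisulfite-sequencing read reports the joint methylated/unmethylated
state of the CpG sites it covers on one DNA molecule, i.e. on one
chromosome of one cell. Over a segment of `b` consecutive CpG sites
(default `b = 4`), each fully covering read therefore contributes one of
`2^b` possible *methylation patterns*, and the empirical pattern
distribution `{n_1, ..., n_k}` (with `N = sum n_i` reads and `k`
observed patterns) estimates the composition of the epiallele population
in the sample. Two summary statistics quantify its heterogeneity:

- normalized Shannon entropy,
  `H = (1/b) sum_i -(n_i/N) log2(n_i/N)`, which is 0 when one pattern
  carries all reads and 1 when all `2^b` patterns are equally frequent
  (the `1/b` factor makes values comparable between `b = 4` and the
  concatenated `b = 8` analysis);
- a Gini index over the *full* pattern space,
  `G = (1/(k-1)) [k + 1 - 2 sum_i (k+1-i) n_i / sum_i n_i]`, computed
  with `k` fixed at `2^b`, counts sorted non-decreasingly and unobserved
  patterns entered as zeros. Fixing `k` at `2^4 = 16` for 4-site
  segments anchors the scale; we extend the same rule to `k = 2^8 = 256`
  for concatenated pairs.

The conventional methylation level `mC/(mC + C)` is reported alongside;
segments with equal levels can have very different entropies, which is
the point of the method.

Assumptions worth making explicit: CpG methylation is treated as
symmetric across strands (both strands' calls collapse onto the
forward-strand C; reads covering the same site from opposite strands are
distinct molecules); a read is used only if it has an unambiguous call
at *every* site of a segment; a diploid cell carries exactly two
epialleles per segment (copy-number variation and cell-cycle effects are
ignored).

## Error filtering and its calibration

Technical errors — incomplete bisulfite conversion, over-conversion, PCR
and sequencing errors — generate spurious rare patterns and inflate
heterogeneity. The filter cascade (`filter_config()`) counteracts this:

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 16 reads | minimum fully covering reads per segment; shallower segments are not scored |
| `min_pattern_reads` | 2 reads | a retained pattern needs at least 2 supporting reads |
| `min_pattern_frequency` | 1/32 | patterns with frequency strictly below 1/32 of the pre-filter total are removed; exactly 1/32 is retained |

Both pattern rules are applied jointly in one pass against the
*pre-filter* `N` (the frequencies are estimated from the identified
patterns before any removal), and the metrics are then computed on the
renormalized post-filter counts, since the discarded patterns are
declared technical artifacts. The pre-filter methylation level is kept
in the output (`meth_level_prefilter`) because the filter targets
heterogeneity, not level.

The calibration standard comes from single cells: per cell and segment,
the two most frequent patterns `A1`, `A2` are candidate epialleles, and
the count ratio `n(A1)/n(A2)` separates heterozygous cells (ratio below
the cutoff) from homozygous cells whose minor pattern is error-derived
(ratio at or above it). The cutoff is 11.5 on the raw ratio — the
bimodal separation is conventionally displayed on a log2 axis, but a
cutoff of `2^11.5` would be unreachable at single-cell depths, so the
stated value is read as the raw ratio; the boundary itself is assigned
to homozygous. When a cell shows a single pattern, a pseudo second
pattern with count 1 is used; if even then the ratio stays below the
cutoff the cell is *indeterminate* — too shallow to exclude an unseen
second allele — and is excluded from the gold standard (and from the
heterozygous fraction). Ties in the top-two ranking are broken by the
canonical integer encoding of the patterns, making calls deterministic.

Pooling `{A1, A2}` (heterozygote) or `{A1, A1}` (homozygote) over the
determinate cells gives the gold-standard entropy over `2 n_cells`
epialleles at `b = 4`. That quantity mixes between-cell and within-cell
(allelic) heterogeneity; concatenating each cell's pair into one 8-site
pattern — canonically ordered, smaller code first, so (A, B) and (B, A)
coincide — and recomputing entropy at `b = 8` over `n_cells` patterns
isolates the cell-to-cell component. The two are strongly correlated on
simulated cohorts (and empirically on real data), which is what licenses
using filtered *bulk* entropy as a proxy for cell-to-cell heterogeneity.

## Segments, regions, outputs

CpG sites are enumerated from the genome FASTA (every `CG`, indexed by
the 0-based forward-strand C; ambiguity codes never form a site).
Segments are sliding windows of `b` consecutive CpG sites. The window
step is configurable and defaults to 1 (overlapping windows), the most
inclusive reading of "all segments of 4 consecutive sites"; `step = b`
yields the non-overlapping tiling when a sparser summary is wanted.

Per-gene aggregation uses five strand-aware regions anchored at the
transcription start and end sites: Upstream1000, Upstream500, GeneBody,
Downstream500, Downstream1000 (the 500-bp windows nested inside the
1000-bp ones), clipped at chromosome bounds. A segment contributes to a
region only if fully contained in it — fractional overlaps would double
count reads between adjacent regions — and region means are unweighted
across segments, with bootstrap standard errors. When one gene name
carries several transcripts, the longest span is used by default
(`collapse = "union"` is available).

Significance of an entropy difference is assessed by permutation: the
statistic is the absolute entropy difference, the minimal statistic
matching "a difference in Shannon entropy". Two exchangeable units are
supported, because both comparisons arise in practice: reads
(re-partitioning the pooled pattern observations of two segments or
samples) and segments (re-partitioning per-segment entropies between two
samples over a region). P-values use the add-one estimator
`(1 + #{permuted >= observed})/(1 + n_perm)`, which can never return 0
at finite `n_perm`; exhaustive enumeration over all re-partitions is
available for small pooled counts and then reports the exact fraction.

Outputs are a per-segment TSV (floats at 6 decimals, rows sorted by
coordinate; coordinates 0-based half-open), bedGraph, and a BED9 track
whose `itemRgb` interpolates linearly from light blue RGB (173,216,230)
at entropy 0 to dark blue RGB (0,0,139) at entropy 1 — the endpoint RGB
values are the conventional named colors, with components rounded
half-up.

## The simulator

`simulate_cohort()` generates the data the estimators are tested
against: per segment, a pool of epiallele patterns with population
frequencies; per cell, two alleles drawn independently from the pool
(diploid); per read, one of the cell's two alleles chosen uniformly,
then corrupted site-by-site — bisulfite non-conversion flips unmethylated
sites to methylated (default 0.005), over-conversion flips methylated to
unmethylated (0.005), and sequencing error flips either direction
afterwards (0.001). The bulk library is the union of all cells' reads
with cell identity erased. Default study conditions: 20 cells and 24
reads per cell per segment — a fixed depth chosen so that a pure
homozygote's pseudo-count ratio (24/1) clears the 11.5 cutoff and allele
pairs are recoverable per cell — and per-segment pools of 1–3 patterns
with symmetric-Dirichlet(2) frequencies, giving a realistic mix of
clonal, skewed and balanced segments across a cohort.

What the simulator does *not* emulate: realistic CpG spacing (segments
are laid out well separated on one synthetic chromosome), partial read
coverage (every simulated read spans its whole segment), coverage
unevenness and dropout typical of scBS-seq, PCR duplication structure
(only an optional uniform read multiplier), and any correlation of
methylation state with sequence context. Passing tests therefore show
that the estimators and filters behave correctly under the stated
generative model, not that real libraries meet that model; on real data
the coverage filter and the indeterminate category absorb much, but not
all, of the difference.

Truth tables record each segment's pool, each cell's realized allele
pair, and the realized-population entropy (`true_population_entropy()`),
which is what the filtered-bulk estimate should recover.

## Numerical choices and degenerate inputs

- Entropy terms for unobserved patterns are 0 (the `p log p` limit);
  only observed patterns enter the sum.
- All arithmetic is double precision; table output prints 6 decimals.
- `N = 0` segments raise an error in the scalar functions; the batch
  drivers represent insufficient coverage as a distinguished dropped (or
  `NA`, with `keep_rejected = TRUE`) row instead.
- Reads with conflicting duplicate calls at a site are excluded from
  that segment rather than arbitrated by majority.
- Sorting ties in output tables break by end coordinate; top-two ties in
  epiallele calling break by pattern encoding.
- The permutation and bootstrap routines run under a caller-supplied
  seed and restore the caller's RNG state; seeds are recorded in the
  results.

## Problem sizes used by the test suite

The calibration checks run on simulated cohorts of 200 segments by 20
cells (recovery and correlation), 60 segments (overestimation
direction), 1000 group pairs at 199 permutations (type-I error), and
exhaustive permutation enumeration at pooled sizes up to 12 reads —
sizes at which the Monte-Carlo tolerances in the tests are comfortably
binomial-bounded while the whole suite stays fast on one CPU.

## Known limitations

Heterogeneity is only measurable where at least `b` CpG sites fall
within one read length, so low-CpG-density regions are invisible at
`b = 4`; longer reads or overlapping read pairs would relax this. BS-seq
conflates 5mC with 5hmC, so the entropy is over the joint mark.
Permutation p-values are per comparison; genome-wide screens need a
multiple-testing strategy downstream. The gold standard treats cells as
independent diploid units — clonal substructure within a cohort is not
modeled.
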