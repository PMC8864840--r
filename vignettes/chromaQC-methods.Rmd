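---
title: "chromaQC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromaQC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromaQC computes a quality-control panel for chromatin occupancy
sequencing (ChIP-seq, CUT&RUN) from standard alignment, peak and
annotation files, classifies every metric on a five-level color-rank
scale, and averages the ranks into a single overall quality score. This
vignette records the models, conventions and design decisions behind
each component, at the level of detail a maintainer or reviewer needs.

## Data model and coordinates

All genomic data live in `GRanges` containers, which use 1-based closed
coordinates. File formats that are 0-based half-open (BED) are converted
at the I/O boundary only: start + 1 on read, start − 1 on write, so a
BED record `chr1 100 200` is `chr1:101-200` internally and survives a
write/read round trip exactly. GTF input (1-based inclusive) maps
directly. Keeping the conversion in one place removes any opportunity
for off-by-one drift between modules; every interval test in the
package (blacklist membership, peak overlap, FRiP) is therefore
equivalent to the half-open test stated in BED terms.

A sequencing read is reduced to a *tag*: its 5′-end base (the leftmost
aligned base of a plus-strand read, the rightmost of a minus-strand
read), its strand, and its read length. The `TagSet` class holds the
tags together with the library-level counts (`totalRaw`, `totalMapped`)
that the library metrics need. Tags, not full alignments, are the unit
of every downstream metric.

## Read filtering

Two filters run in a fixed order: duplicate removal, then blacklist
removal. The duplicate key is (chromosome, 5′ position, strand) — read
length is deliberately excluded, since two single-end reads starting at
the same base are redundant regardless of trimming. The first tag per
key, in input order, is retained. The blacklist test uses the tag's 5′
position only (configurable in spirit but the 5′ convention is used
throughout, so that every metric counts the same objects). Because the
non-redundant fraction is computed *before* any filtering, the
blacklist choice can never change NRF or PBC.

## Library metrics

* **Aligned percent** `A = 100 · mapped / raw`.
* **NRF** = distinct tag keys / mapped tags. The mapped-read
  denominator follows the ENCODE library-complexity convention.
* **PBC** = keys seen exactly once / keys seen at least once.
* **Base quality** and **sequence diversity** are pass/warn/fail flags
  over a FASTQ sample (default cap 10⁶ reads, a desk-scale bound at
  which the per-cycle statistics are stable). The thresholds are the
  FastQC conventions: base quality fails when any cycle has
  lower-quartile < 5 or median < 20 and warns at < 10 / < 25; diversity
  fails when one exact sequence exceeds 1% of sampled reads and warns
  above 0.1%. Both metrics are reported missing, and excluded from the
  overall score, when no FASTQ is supplied.

## Strand cross-correlation

For each chromosome, the plus-strand and minus-strand distinct 5′
positions form binary occupancy vectors of the chromosome length
(1 bp bins; duplicates are removed upstream). For a shift *s* the
correlation is the exact Pearson correlation between the plus vector
over `[1, N − s]` and the minus vector over `[s + 1, N]`. For binary
vectors this has a closed form in the set sizes and the co-occurrence
count, which is how it is computed — no length-N arithmetic per shift.
Chromosome curves are combined as a tag-count-weighted mean;
chromosomes with fewer than 200 tags, or shorter than the largest
shift, are skipped. The default grid is 0–500 bp in 5 bp steps,
covering typical sonication and nuclease-release fragment sizes.

Derived quantities:

* **Fragment width**: the shift maximising the curve outside the
  *phantom window* (mean read length ± 10 bp, mirroring the ±10 bp
  tolerance of the tag-length metric).
* **Predicted tag length**: the shift maximising the curve inside the
  phantom window; `E` is its absolute deviation from the mean read
  length. When no grid point falls in the window the prediction falls
  back to the mean read length with a warning and `E = 0`.
* **Background**: the minimum of the curve over the grid. The source
  material does not define the background operationally; the grid
  minimum is the most conservative choice (it can only make NSC
  smaller) and is what makes `NSC ≥ 1` a structural guarantee whenever
  the background is positive. A zero-centred curve (no strand
  structure at all) can have a non-positive minimum, in which case NSC
  is reported missing rather than as a meaningless ratio.
* **NSC** `= max(cc) / background`; **RSC**
  `= (cc_fragment − background) / (cc_readlength − background)`.

## Peak metrics and stitched regions

**FRiP** is the fraction of filtered tags whose 5′ position lies in the
union of the (blacklist-filtered) peaks; the union guarantees
overlapping peaks never double-count a tag.

**Stitching** merges peaks transitively when the gap between them is at
most the stitch distance (default 12 500 bp, the ROSE convention; TSS
exclusion is not applied by default). **Signal** of a stitched region
is the sample tags-per-million in the region minus the control
tags-per-million when a control is given, floored at zero — negative
densities are artifacts of sparse controls, not evidence of depletion.
Tag totals use post-filter counts. Regions are ranked by ascending
signal with ties broken by genomic position.

**Super/typical separation** rescales rank and signal to the unit
square and looks for the point where the discrete forward slope of the
curve exceeds 1 — the slope-1 tangent of the classic hockey-stick
picture. One refinement matters: the rule fires only where the slope
exceeds 1 *and stays above it for the remainder of the curve*. On a
convex curve this is identical to the first crossing (for the dense
`y = x²` curve the cutoff is the signal at `x = 0.5`, i.e. a quarter of
the maximum, exactly the analytic tangent point), but on a flat noisy
curve — where roughly half of all forward-difference slopes exceed 1 by
chance — the unqualified first-crossing rule would fire almost
immediately and mark nearly every region "super". With the persistence
qualifier a noise curve yields zero or a handful of supers, an exactly
linear curve yields none, and an isolated strong outlier is always
recovered. The price is deliberate: a set of *exactly tied* top
signals produces a zero slope at the top of the curve and no super
call; real ranked signal curves are graded continua, and a tie among
the strongest regions carries no evidence for a two-population split.
Regions strictly above the cutoff signal are super; `S` is the super
count over the region count.

## Coverage profiling and annotation

Promoter matrices count tag density in fixed-width bins (default 50 bp)
across ±2 000 bp around each TSS; metagene matrices use fixed 50 bp
flank bins over 2 000 bp plus 100 equal-fraction bins across the gene
body. All densities are per-bp, scaled to tags-per-million, which makes
the body rescaling length-fair: doubling a gene's length under uniform
coverage leaves its per-bp densities unchanged. Bins are laid out in
transcription order and mapped to genomic coordinates by strand, so a
minus-strand gene is the exact mirror of the equivalent plus-strand
gene — this is an exact symmetry of the implementation, not an
approximation, and is tested as such. Bins that extend past a
chromosome end use their truncated width; bins entirely off the
chromosome are NA and are excluded from column means. Tags are
optionally extended to the cross-correlation fragment width in the
strand direction (the pipeline default), which is what makes promoter
profiles reflect occupancy rather than read ends; the 5′-only mode is
used wherever an exact counting oracle is wanted.

Peak annotation assigns each peak one category by precedence:
promoter (±1 000 bp of a TSS) ≻ gene body ≻ gene-centric window ≻
intergenic, with ≥1 bp overlap. The *gene-centric window* is defined
here as the gene body extended 10 000 bp on both sides — the source
material names the region types but fixes no sizes, so all four
geometry parameters are exposed. The nearest gene of a peak is the one
whose TSS is closest to the peak midpoint, with signed distance
(midpoint − TSS) and 0 when the peak covers the TSS.

## The rank dashboard

Each metric is classified on the five-level scale Excellent / Good /
Average / Below-average / Poor, with numeric scores 2 / 1 / 0 / −1 /
−2. The score values are forced by the overall-quality thresholds: Q,
the arithmetic mean of the scores of ranked metrics, can only reach
the "≥ 2" band if the scale tops out at 2. Graded thresholds are
applied top-down with inclusive `≥` at every boundary (so a value
exactly at a printed boundary takes the higher band — a property
tested across all thirty-plus published thresholds). Pass/warn/fail
metrics map to Excellent/Average/Poor; `E` is Excellent below 10 bp
and Poor otherwise; NSC has a single boundary at 1.045 and RSC
boundaries at 1 and 0.75. Metrics that cannot be computed from the
supplied inputs (no FASTQ, no control peak set) are reported as
missing and excluded from Q rather than scored 0 — absence of an
optional input should not penalise quality. Unranked metrics
(estimated fragment width, read length, the super-region count) are
shown unflagged.

The report is written as a TSV (metric, value, rank, score) and a
self-contained HTML table whose rank cells are background-colored with
a diverging green-to-red palette (#1a9850, #91cf60, #fee08b, #fc8d59,
#d73027). Formatting is fixed (ratios 4 decimals, percentages 1
decimal, counts with thousands separators) and nothing time- or
environment-dependent enters the output, so re-rendering a panel is
byte-identical — the determinism the end-to-end tests assert.

## The synthetic-data generator

`simulateTags` emulates a single-end chromatin experiment on a toy
genome (default two 1 Mb chromosomes, which keeps a full QC run in
seconds): each fragment lands in a peak with probability `fripTarget`
(peaks chosen width-weighted, position uniform) or uniformly on the
genome, and is sequenced from *both ends*, emitting a plus tag at its
first base and a minus tag at its last. Both-end emission is what
gives the cross-correlation a genuine fragment-length peak. Fragment
lengths are normal with mean `fragmentLength` and standard deviation
`fragmentSd` (default 15 bp, a tight size selection): real libraries
are size-distributed, and it is this dispersion that makes the
correlation peak a smooth bump a 5 bp shift grid can localise — a
constant fragment length would concentrate the pairing signal in a
single 1 bp lag that the grid almost always misses. Each tag is then
duplicated (one extra copy) with probability `duplicateRate`.

All ground truth is tallied *from the emitted tags*, not from the
generator's intentions: distinct keys, singleton keys and
in-peak-after-deduplication counts are exact, so measured NRF, PBC and
FRiP must equal the truth ratios exactly, not approximately — the
strongest kind of recovery test the design allows. Every random draw
sits behind one explicit seed and the generator restores the global
RNG state, so fixed seeds give byte-identical fixtures.

What the generator does not emulate: base-calling errors, GC and
mappability bias, chromatin-structure background, and the
read-length "phantom" peak itself (which arises from mappability
structure absent in a toy genome). Consequently the predicted tag
length on simulated data reflects the smooth curve inside the phantom
window rather than a genuine phantom spike, and passing tests say
nothing about phantom-peak behaviour on real data. The
strand-independent null (`simulateNullTags`) places the two strands
independently and uniformly; its correlation curve is zero-centred, so
the curve is flat (|cc| well under 0.05) and NSC is typically reported
missing — the correct "no enrichment" outcome under the
minimum-over-grid background definition.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated
data: oracle-equivalence checks use 100 randomised instances of ~30
tags and ~15 intervals against brute-force enumeration; fragment-width
recovery uses 20 seeded runs at each of 100/150/200/300 bp with 50 000
fragments and requires the estimate within one grid step (5 bp) in at
least 95% of runs; the reference experiment in
`scripts/acceptance.R` uses 20 genes with TSS-proximal peaks, two of
them broader (5x and 10x) to give the super-region caller a graded
pair of signal-rich loci. These sizes were chosen so the whole suite
is a desk-scale computation while leaving every statistic far from its
decision boundary.

Tie-breaks and degeneracies are fixed as follows: equal
cross-correlation maxima resolve to the smallest shift; equal region
signals rank in genomic order; a cutoff curve whose final slope never
exceeds 1 yields zero supers; identical signals yield a warning and
zero supers; division-by-zero cases (zero mapped reads, non-positive
correlation background, phantom correlation equal to background, empty
region sets) all yield missing values that propagate to unflagged
report rows, never NaN arithmetic.

## Limitations

* Single-end tags only; mate information in paired-end input is not
  used for fragment inference.
* The background of the cross-correlation is the grid minimum; tools
  that define it as the correlation at the largest shift will report
  slightly different NSC on the same data.
* Peak calling is consumed, never performed; the quality of the peak
  metrics is bounded by the peak caller upstream.
* The HTML report is a static single-sample table; no cross-sample
  aggregation.
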