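---
title: "Calling Ta-subfamily L1Hs insertion junctions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling Ta-subfamily L1Hs insertion junctions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebelkit)
```

## The measurement model

Ta-subfamily L1Hs elements carry diagnostic nucleotides in their 3′ UTR
that a nested amplicon protocol can prime on, so each sequencing
library is, ideally, a pile of read-1 molecules that begin inside the
element's 3′ end and extend into the downstream genomic flank. After
alignment to a reference genome, the footprint of one insertion is a
cluster of reads whose *start* coordinates sit within a short interval
on one strand, anchored at the insertion junction. Three consequences
drive the design:

* read starts, not read extents, carry the junction signal — clustering
  is therefore on starts;
* the cluster strand is determined by which genomic strand the flank
  was read on, and is systematically *opposite* the element's strand;
* reads that run through the junction the other way pick up the
  element's poly(A) tail, appear as poly(T) in read orientation, and
  fail to align until the tail is trimmed.

The pipeline's atom is an aligned read `(chrom, start, end, strand,
MapQ, sample)`; all intervals are 0-based half-open (BED convention),
converted once at the SAM boundary (`start = POS − 1`, `end` from the
reference-consuming CIGAR length). Unmapped, secondary and
supplementary records are never used; MapQ filtering keeps one
confident placement per read.

## Peak calling

Within each (chromosome, strand) partition, reads sorted by start are
chained by single linkage with gap threshold *w* (default **150 bp**):
a read joins the open cluster when its start is within *w* of the
largest start already in the cluster. This equals connected components
of the relation |startᵢ − startⱼ| ≤ *w*, which gives three properties
the tests rely on: independence of input order, invariance to
splitting the input by chromosome, and monotonicity (a larger *w*
never produces more peaks). The published method describes a sliding
window without fixing whether it anchors on the first or the latest
read of a cluster; the chaining (sliding with the latest read) reading
was chosen precisely because it has an order-free characterisation
that an independent oracle can check.

Per peak we record total reads, per-sample counts, mean MapQ, and
"unique reads" defined as distinct (sample, start) pairs — a
PCR-duplicate-insensitive count (strand is constant within a peak; the
underlying method does not define uniqueness, so the conventional
amplicon deduplication was adopted). Single-read peaks are emitted:
every cutoff is a later, explicit, reportable stage.

## Annotation

Each peak is extended **500 bp** downstream *with respect to its own
strand* (`+`: `[s, e + 500)`; `−`: `[max(0, s − 500), e)`) and
intersected with two catalogs: a repeat-masker-style reference L1Hs
track and a known non-reference insertion track. Precedence is
reference > known non-reference > novel non-reference, so
classification is exhaustive and exclusive. Half-open arithmetic makes
"within 500 bp" inclusive: a feature whose nearest base is exactly
500 bp beyond the peak edge is reached, one at 501 bp is not (both
boundaries are tested).

Feature strand is ignored by default. The phrase "with respect to
strand" qualifies the direction of the peak's extension, not a strand
match — under the junction geometry above, peak and element strands are
systematically opposite, and demanding equality would discard every
true hit. A strict same-strand mode
(`require_feature_strand_match = TRUE`) exists for users whose catalog
records junction orientation rather than element orientation; users
aligning against real repeat-masker tracks should check which
convention their track uses. Ties among overlapping features break by
distance from the peak's downstream edge, then lexicographic name —
an arbitrary but deterministic rule.

## Filters

**Index hopping.** Free adapter exchange mis-assigns a small fraction
of reads between samples multiplexed in one pool, creating spurious
low-count carriers. Per pool and per peak, counts strictly below
**6%** of the pool's maximum are zeroed (a count exactly at the
threshold survives; the rule is "less than"). Pools are independent.
The filter is idempotent — the pool maximum can never be zeroed, so a
second pass sees the same threshold — and this is asserted on random
tables rather than argued only on paper. After remediation the
read-level members of a peak are no longer available, so
`n_unique_reads` and `mean_mapq` keep their calling-stage values while
totals and carrier-derived quantities are recomputed; peaks losing
every count are dropped and counted.

**MapQ cutoff.** Reference-catalog insertions are almost certainly
real, so the distribution of their per-peak mean MapQ calibrates a
quality bar for everything else: mean − 2 × SD, with the sample (n−1)
standard deviation. The population/sample choice is immaterial at
cohort scale (with the published inputs 38.82 ± 4.10 both give 30.62)
but must be fixed for reproducibility; n−1 was chosen.

**Read-depth cutoff.** Average reads per carrier = total reads /
number of carriers (samples with a positive remediated count);
threshold **100**, applied after the MapQ cutoff. Retention is
reported per class and per stage, with percentages relative to each
class's pre-cutoff count, rounded to 2 decimals — the convention that
reproduces the published 66.57% = 699/1050 for the joint filter.

## Validation calculus

Surviving peaks are binned by average reads per carrier into
[100, 250), [250, 500), [500, 1000), [1000, ∞). For each bin, the PCR
validation rate of sampled novel calls (`validated/attempted`, as a
percentage rounded to 1 decimal) scales the count of detected novel
calls into predicted true positives; known and reference detections
count as true outright. Two rounding conventions were genuinely open
and are fixed as follows:

* predicted true positives multiply the detected count by the
  *rounded* percentage, then round half away from zero — the only
  convention consistent with all four published rows (460 × 72.7% =
  334.42 → 334, whereas the unrounded ratio would give 334.5…);
* cumulative precision for "this bin and above" accumulates the
  already-integer per-bin true-positive totals, matching a table built
  from its own printed cells.

All percentage rounding is half away from zero (base R's `round()`
is round-half-even and disagrees at exact midpoints). A bin with zero
validation attempts is an error, not a silent `NaN`.

## The simulator

`sim_config()` defaults define the simulated study conditions: pools
of **6** multiplexed samples (12 samples, 2 pools), junction-anchored
reads of **150 bp** jittered uniformly within one clustering window of
the junction, Poisson read depth per carrier (mean 300), MapQ from a
rounded normal **39 ± 4.1** clamped to [0, 60] (placing a small tail
below the MapQ-30 filter, as observed for reference insertions), a
**10%** poly(T) diversion rate among non-reference-supporting reads
(the observed share of unalignable reads with poly(T) tails — treated
here as a generative rate, an approximation), and a **1%** index-hop
rate. Reference insertions are carried by every sample; non-reference
carriers are Bernoulli draws from a per-insertion allele frequency
uniform on [0.1, 0.9], forced non-empty.

Junctions are placed uniformly with ≥ 2 kb separation (a
sorted-uniform construction, so placement never loops). Catalog
features are 500 bp element intervals starting 300 bp downstream of
the junction on the opposite strand. These two lengths are chosen
jointly: a peak spans at most jitter + read length ≈ 300 bp beyond its
junction, annotation reaches 500 bp further, and
300 + 500 + 500 + 300 = 1600 < 2000, so a neighbouring insertion can
never capture another insertion's feature and class labels in the
truth set are exact. Diverted poly(T) reads carry a T-free genomic
portion (length 90–135 bp) followed by a 15–60 bp poly(T) tail, so the
planted tail is the unique trimmable signal.

`make_truth()` seeds the generator with `seed` and `simulate_reads()`
with `seed + 1`: truth and reads come from documented stream
positions, and identical configurations are byte-reproducible.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: real genome sequence and
alignability (reads are placed, not aligned; mapping ambiguity in
repeats is represented only through the MapQ distribution),
restriction-fragment end structure, base-call errors, chimeric PCR
artifacts, read 2, and the 5′-truncation spectrum of real elements.
The end-to-end recovery results are a correctness check of the
pipeline's logic under its own geometric model, not an accuracy claim
for human cohorts.

## Poly(T) trimming

`find_polyt()` scans every k-mer window (default **k = 11**, at most
**1** non-T base, `N` counting as non-T) and right-trims at the
leftmost qualifying window; reads retaining fewer than **25 bp**
(a conservative alignability floor — the underlying method states no
minimum) are rejected rather than realigned. Two documented
consequences of "leftmost window, Hamming distance 1": when a pure
poly-T tail follows a non-T base, that base is absorbed as the
window's one mismatch and the cut lands one base before the tail; and
trimming is *not* idempotent — the retained prefix may itself contain
a qualifying window — so a second pass may trim further. Equivalence
with a brute-force all-windows oracle is asserted on randomized reads.
Untrimmed reads pass through unchanged for realignment.

## Problem sizes in the checks

The shipped checks use: 500 random instances of up to 200 reads for
the clustering-vs-transitive-closure equivalence (plus windows 1, 50
and 150 bp in the unit suite); 1,000 random 30–150 bp reads for the
trimming oracle; a 50-insertion noise-free cohort for exact end-to-end
recovery; a 200-insertion cohort at 1% hopping for carrier-set
restoration; and the full published validation/retention inputs for
the exact arithmetic checks. These sizes give the properties room to
fail (hundreds of thousands of reads pass through the callers) while
keeping the default test run brisk.

## Known limitations

* Breakpoints are peak intervals, not base-pair-resolved junctions; no
  target-site-duplication detection, genotype likelihoods or split-read
  assembly.
* Merging the original and trimmed-realignment SAMs may duplicate read
  ids; duplicates are accepted (and inflate counts symmetrically), not
  deduplicated.
* The peak/element strand convention is self-consistent between
  simulator and annotator but unverified against any specific public
  repeat-masker release; the strict strand-match mode is provided for
  catalogs with known orientation semantics.
* BAM input is supported via the same reader (`read_sam()` accepts
  `.bam`), but CRAM and VCF emission are out of scope.
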