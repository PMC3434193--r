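---
title: "Repeat-aware differential binding and TE expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware differential binding and TE expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcripts derived from transposable elements (TEs) and other repeats are
systematically discarded by analyses that keep only uniquely mapped reads:
a read from a young TE family aligns equally well to tens or hundreds of
near-identical genomic copies. repclip implements a repeat-aware analysis of
protein–RNA interaction libraries (CLIP-seq, RIP-seq) and of mRNA-seq,
built around fractional weighting of multi-mapped reads, so that binding
and expression of repeat elements can be quantified rather than thrown
away.

This vignette records the models, the parameters that matter, and the
design decisions taken where more than one reasonable choice existed.

## Alignment weights and mapping strategies

Every reported alignment of a read receives weight $1/n$, where $n$ is the
number of reported alignments of that read (after the reporting cap
`m_cap`). The total weight of each mapped read is therefore exactly 1, and
weights carry no contribution from mapping quality — all reported
alignments are treated as equally plausible origins. All downstream
counting (bins, windows, elements) sums these weights.

Three strategies control which reads enter an analysis:

* **UNIQ** — uniquely mapped reads only. Unbiased about location, blind to
  young, low-divergence families.
* **UNIQ+SameEle** — additionally keeps a multi-mapped read when a single
  repeat *Element* (subfamily, e.g. L2b) has instances overlapping every
  one of its alignments. Matching is at the Element level, not the
  Instance level, because instance identity is exactly what multi-mapping
  obscures; the overlap predicate is ≥ 1 bp.
* **MULTI** — all weighted alignments.

The read sets nest (UNIQ ⊆ UNIQ+SameEle ⊆ MULTI), which the test suite
asserts as an invariant.

PCR duplicate removal operates on whole reads. Without barcodes, a read's
key is the (5′ position, strand) of its lexicographically smallest
alignment, and one read per key survives — the same primary-alignment
logic as conventional duplicate marking. We key whole reads rather than
individual records because exact sequence copies share *every* alignment;
removing the duplicate read removes all of its records and the per-read
weight-conservation invariant (weights of a retained read sum to 1)
survives deduplication. When random barcodes are available they join the
key, so genuinely distinct molecules at the same position are kept.

One practical consequence, visible in the tests: at high local coverage,
position-based deduplication saturates (distinct 5′ positions run out), so
deduplicated counts over strongly enriched loci are deflated relative to
the planted fold. Tests that check fold recovery therefore simulate
without planted duplicates and skip deduplication; the pipeline applies it
by default because real libraries contain PCR duplicates.

## Bin-correlation normalisation

Library-size (RPM) scaling assumes the genome-wide background is
comparable between libraries, which fails when one library is dominated by
a few massive regions (rRNA repeats in control IPs being the classic
case). Instead, the genome is cut into adjacent non-overlapping bins
(default 10 kb); each alignment contributes its weight to the single bin
containing its midpoint (boundary midpoints fall into the right-hand bin),
so a read is counted at most once overall. The library with the largest
total is the reference $L_r$. For every other library $L_i$, bins whose
pairwise maximum count exceeds the `q`-th quantile (default 0.75) are
excluded as presumptive signal, and over the remaining low-abundance
background bins a zero-intercept least-squares line $L_i \approx e_i L_r$
is fitted; the slope $e_i$ is the scale factor and counts are reported on
the reference scale as $k/e_i$.

Two notes on this design:

* A correlation coefficient cannot rescale totals, so the factor is
  implemented as the regression slope of the stated linear relation; this
  is the quantity that makes $L_i \approx e_i L_r$ meaningful.
* Selecting bins by a pairwise-max quantile truncates the joint
  distribution and introduces a small bias in the slope. At `q = 0.75` on
  Poisson backgrounds the bias is a few percent; at `q = 0.9` it is under
  3%. The tests check scale equivariance at `q = 0.9` for this reason; `q`
  is exposed and the default favours robustness to genuine signal over the
  last few percent of bias.

## Windowed differential binding

The genome is scanned with 500 bp windows advanced by 100 bp (overlapping
windows refine the resolution at which region boundaries can be placed).
An alignment contributes its weight to every window it overlaps. Windows
with zero total count are not tested; the Benjamini–Hochberg correction
runs over the tested windows only.

For a window with normalised counts $k_A$ (IP) and $k_B$ (control),
conditioned on the total $k_S = k_A + k_B$, the p-value is

$$
p = \frac{\sum_{a+b=k_S,\; p(a)p(b) \le p(k_A)p(k_B)} p(a)\,p(b)}
         {\sum_{a+b=k_S} p(a)\,p(b)},
$$

where $p(\cdot)$ is a Poisson mass function, or a negative binomial with
variance $\mu + \alpha\mu^2$ when replicates allow estimating the
dispersion $\alpha$ ($\alpha = 0$ recovers Poisson exactly). Numerical
choices:

* Weighted counts are fractional; mass functions need integers, so counts
  are rounded to nearest with ties to even before testing.
* Ties in the $p(a)p(b) \le p(k_A)p(k_B)$ comparison are included, with a
  relative tolerance of $10^{-9}$ so floating-point noise cannot exclude
  an exact tie.
* The sum is normalised by the total conditional probability, so the
  p-value lies in $(0, 1]$ and equals 1 when the observed split is the
  conditional mode.
* Null means are split proportionally to the library scales — 1:1 once
  counts are normalised to the reference scale — so under the Poisson
  model the conditional null is Binomial$(k_S, 1/2)$. The test suite
  verifies the implementation against an independent conditional-binomial
  oracle as well as direct enumeration, for all totals up to 50.

The dispersion $\alpha$ is estimated by method of moments: per-window
means $m$ and variances $v$ within each condition, pooled by a
zero-intercept least-squares fit of the excess variance $v - m$ on $m^2$;
the slope is $\alpha$, clamped at 0. This is deliberately simpler than a
local regression of variance on mean — it is unbiased under the quadratic
variance model and recovers $\alpha = 0.5$ within ±0.15 at $10^4$ windows
in the tests.

Significant windows (adjusted $p$ below `alpha`, default $10^{-5}$, with
an optional fold filter) merge into regions when they share a direction
and are separated by a gap strictly smaller than `merge_gap` (default
500 bp). Merging is idempotent and order-independent. A region's
`peak_height` is the maximum per-base normalised IP coverage within it —
"height" is not otherwise defined for a merged region, and max-coverage is
the conventional reading; the same position serves as the region's
crosslink-proxy centre for motif analysis.

Element-level testing aggregates weighted counts over all instances of
each repeat Element (an alignment overlapping two instances of one Element
counts once), then applies the same exact test and BH correction across
Elements. Both the window-level and element-level routes are available;
element-level is the default unit for cross-run comparisons because
instances are not identifiable for multi-mapped reads.

## Annotation

Regions are labelled with a strict precedence: any exon overlap ⇒
`RefGene` (even when a repeat instance lies inside that exon); otherwise
any repeat overlap ⇒ `repeat`, named by Element, with ties broken by
largest overlap then leftmost instance; otherwise `intergenic`.
Simple-repeat instances overlapping instances of other repeat classes are
removed before labelling. Strand is ignored for annotation: CLIP reads map
antisense to TE annotations about half the time and are deliberately
counted. A separate `genic_context` records exonic/intronic/intergenic
placement regardless of the label, which supports the
fraction-of-targets-that-are-intergenic summary.

## Positional pentamer enrichment

Around each binding-site centre, for every offset in $[-25, +25]$, the
number of sites whose genomic sequence carries the pentamer (default
UGUGU, the characteristic UG-rich TDP-43 motif) starting at that offset is
counted on the site's strand. The null repeats the computation on
`n_random` (default 100) site sets drawn uniformly from the same
annotation category's intervals, matched in count; enrichment per offset
is observed over null mean, defined only where the null mean is positive.

The sparse regime matters here: with few sites, many offsets have null
mean zero and the enrichment curve is undefined there. The profile
reports the raw observed, null mean and null SD so users can judge; the
tests use site sets dense enough (hundreds of sites) that every offset
has a positive null. Site sets whose positions are lattice-aligned to
their annotation (e.g. always the interval centre) are *not* exchangeable
with the uniform null and can show spurious dispersion; site centres
derived from data (coverage maxima) do not have this problem.

The RefGene/repeat contrast is the ratio of the two enrichment curves'
maxima. Its sampling robustness is assessed by recomputing the ratio for
two conditions on repeated 50% subsamples of the sites and reporting the
fraction of iterations in which the conditions' ordering reverses. The
randomised nulls are computed once per (annotation space, site count) and
shared across conditions — identical inputs then give identical ratios,
and the null mean for a subsample is the full-data null mean scaled by
the subsample fraction (it is linear in site count). Exact ties count as
half a reversal, so identical conditions sit at 0.5 by construction
rather than at an arbitrary 0 or 1.

## Crosslink sites without a control

When no control library exists, reads are reassigned uniformly at random
to the annotated (gene + repeat) space, 100 times; a site is a position
with at least one read start. For an observed per-site count $x$ with
observed frequency $p_x$, the score is
$p^{adj}(x) = (\mu_x + \sigma_x)/p_x$ with $\mu_x, \sigma_x$ the mean and
SD of the frequency of $x$ across randomisations (iterations where $x$
never occurs contribute frequency 0). A count never produced by the
background gets $p^{adj} = 0$ — maximally significant — and is logged.
The default call cutoff is $p^{adj} < 0.01$ and is configurable.

A uniform background is knowingly wrong for gene transcripts (transcription
is not uniform); the module's report header carries this caveat, and calls
from this route should be treated as weaker evidence than control-based
differential binding.

## TE expression

Element abundance from mRNA-seq is the sum of alignment weights falling
within the Element's instance boundaries *on the annotated strand*
(expression counting is strand-correct, unlike CLIP counting), divided by
the Element's total instance length. Differential abundance between
conditions uses median-of-ratios size factors, integerised element-level
weight sums, and the same conditional exact test as differential binding
(with a moments dispersion estimate when both conditions have at least two
replicates); per-length abundances are for reporting only and are not fed
to the test, because the test's count model needs counts, not rates.

## The synthetic-data generator

The generator is first-class, tested code: it produces genomes whose
chromosome backgrounds are uniform random DNA, with planted multi-copy
repeat families (a random consensus per family; each copy mutated at the
family's divergence rate, so divergence 0 forces multi-mapping and high
divergence yields unique reads), gene models with non-overlapping exons,
and read libraries with planted per-base fold enrichment over chosen
Elements or genes, optional planted pentamers at target centres, exact
PCR duplicates at a stated rate, and configurable strand fidelity
(defaults: 0.5 for IP/control — crosslinked fragments come off both
strands; 1 for expression libraries). By default 20% of TE copies are
placed inside introns and the rest intergenic. Reads are single-end,
fixed-length and error-free: inter-copy divergence, not sequencing error,
drives the unique/multi-mapping split, which keeps the exact-match toy
aligner faithful. All outputs are pure functions of their seeds.

What the generator does *not* emulate: sequencing error and base
qualities, paired ends, splicing, fragment-length or crosslink-position
chemistry (site-centre sampling is the single knob), and realistic genome
composition (GC structure, nested repeats). Passing tests therefore show
that the statistics behave correctly under their stated models — not that
those models capture every property of real libraries.

## Problem sizes used by the tests

The suite exercises the full pipeline at deliberately small scale: module
tests use 50–200 kb genomes with $10^3$–$4\times10^4$ reads; the
end-to-end recovery checks use a 1 Mb genome with 100 two-copy families
and $10^5$ reads per library across 10 seeds, where 20 planted 8-fold
enriched Elements must be recovered with sensitivity ≥ 0.9 and zero false
Elements at adjusted $p < 10^{-5}$; exact-test oracle equivalence is
checked exhaustively for all window totals up to 50. These sizes were
chosen so that expected counts match the regimes the statistics are meant
for (tens to hundreds of reads per tested unit) while the whole suite
runs in a couple of minutes.

## Known limitations

* The exact-match toy aligner admits no mismatches; reads from copies
  diverged by even one substitution within the read map uniquely. Real
  aligners with mismatch tolerance blur this boundary.
* Position-based deduplication saturates at high coverage (above).
* Overlapping windows are tested without any correction for their spatial
  autocorrelation; the BH correction treats windows as independent tests.
* The no-control background ignores non-uniform transcription.
* Bin selection for normalisation happens per pair against the reference,
  not jointly across more than two libraries.
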