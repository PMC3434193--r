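# repclip

Repeat-aware analysis of CLIP/RIP-seq binding and transposable-element
(TE) expression.

Standard short-read analyses keep only uniquely mapped reads, which
silently removes transcripts derived from TEs and other repeats — a read
from a young TE family aligns equally well to many near-identical genomic
copies. repclip keeps those reads: every reported alignment of a read
receives weight 1/n (n = number of reported alignments), so each read's
total weight is exactly 1, and all counting, normalisation and testing
downstream operates on these weights.

The package provides, as plain R functions:

* **Weighted alignment records** — a toy exact multi-mapper for synthetic
  genomes, uniform 1/n weight assignment, PCR-duplicate removal, and the
  three mapping strategies **UNIQ** (unique reads only),
  **UNIQ+SameEle** (plus multi-reads whose alignments all fall in
  instances of one repeat Element) and **MULTI** (all weighted reads).
* **Bin-correlation normalisation** — per-library scale factors `e` fitted
  as the zero-intercept regression slope `L_i ≈ e_i · L_r` over
  low-abundance background bins (default 10 kb), so dominant regions such
  as rRNA repeats cannot bias the scaling as they do with library-size
  (RPM) factors.
* **Differential binding** — 500 bp windows stepped by 100 bp, tested with
  a conditional exact test: conditioning on the window total
  k_S = k_A + k_B, the p-value sums the probabilities of all splits
  (a, b), a + b = k_S, with p(a)·p(b) ≤ p(k_A)·p(k_B), under Poisson or
  negative-binomial (variance μ + αμ²) models, BH-corrected, thresholded
  at adjusted p < 1e-5, and merged into regions across same-direction gaps
  < 500 bp. The same test aggregated over all instances of each repeat
  Element gives element-level enrichment.
* **Annotation** — RefGene/repeat/intergenic labels with exon-wins
  precedence, the four-level repeat hierarchy
  (Class/Family/Element/Instance), simple-repeat exclusion, and
  Element-level set comparison across runs and strategies.
* **Motif enrichment** — positional UGUGU pentamer counts in [-25, +25] nt
  around binding-site centres, normalised against 100 randomised site
  sets from the same annotation category, with a RefGene/repeat
  peak-enrichment ratio and a 50%-subsampling robustness test.
* **No-control peak calling** — crosslink-site significance
  p_adj(x) = (μ_x + σ_x)/p_x against a randomised read-assignment
  background iterated 100 times.
* **TE expression** — strand-correct, length-normalised per-Element
  abundance from mRNA-seq, differential abundance via median-of-ratios
  size factors plus the same exact test, and concordance of mis-expressed
  Elements with CLIP binding targets.
* **Synthetic data** — genomes with multi-copy TE families of tunable
  inter-copy divergence (divergence 0 forces multi-mapping), gene models,
  and IP/control/expression libraries with planted fold enrichment,
  planted motifs, PCR duplicates and strand structure, all with truth
  tables; every downstream stage is testable without external downloads.

## Worked example

A 100 kb synthetic genome carries two repeat families — `L1_A` (three
identical copies, so its reads multi-map) and `B1_B` (three copies at 20%
divergence) — and the IP library is enriched 8-fold over `L1_A`:

```r
library(repclip)

spec <- genome_spec(100000,
  te_families = list(
    te_family("L1_A", "LINE", "L1", n_copies = 3, divergence = 0),
    te_family("B1_B", "SINE", "B1", n_copies = 3, divergence = 0.2)),
  n_genes = 4, seed = 42)
g <- build_genome(spec)

ip  <- simulate_library(g$genome, g$repeats, g$genes,
         library_spec("IP", n_reads = 20000,
                      enriched_targets = c(L1_A = 8), seed = 11))
ctl <- simulate_library(g$genome, g$repeats, g$genes,
         library_spec("control", n_reads = 20000, seed = 12))

rec_ip  <- remove_duplicates(toy_align(ip$reads,  ip$genome,  m_cap = 100))
rec_ctl <- remove_duplicates(toy_align(ctl$reads, ctl$genome, m_cap = 100))

bins <- bin_counts(list(IP = rec_ip, control = rec_ctl), g$genome,
                   bin_size = 1000)  # 1 kb bins: toy genome, 100 bins
(f <- estimate_factors(bins))
#> Bin-correlation normalisation factors
#>   reference library: control
#>   IP           e = 0.9551  (total 18332.0, 79 bins)
#>   control      e = 1.0000  (total 19041.0, 100 bins)
```

The control library has slightly more retained reads, so it is the
reference; the IP library's counts are divided by e = 0.955 to put both on
one scale. Scanning, testing and merging finds exactly the three planted
`L1_A` copies:

```r
wins <- window_test(scan_windows(rec_ip, rec_ctl, g$genome, f,
                                 libs = c("IP", "control")))
regions <- merge_regions(wins,
  coverage = weighted_coverage(rec_ip, g$genome, f$e[["IP"]]))
regions
#>     chrom start   end direction n_windows best_p_adjusted peak_height
#> 1:   chr1 50801 51700  enriched         5    8.354188e-15    34.20185
#> 2:   chr1 73001 73800  enriched         4    5.825517e-12    32.10786
#> 3:   chr1 84201 85100  enriched         5    2.368841e-15    34.20185

element_enrichment(rec_ip, rec_ctl, g$repeats, f,
                   libs = c("IP", "control"))[,
  .(element, class, k_a, k_b, log2fc, p_adjusted, direction)]
#>    element  class      k_a   k_b      log2fc   p_adjusted direction
#> 1:    L1_A   LINE 642.8552   188  1.77105106 1.207796e-58  enriched
#> 2:    B1_B   SINE 176.9422   183 -0.04843056 7.921913e-01  depleted

annotate_regions(regions, g$genes, g$repeats)[,
  .(chrom, start, end, category, name)]
#>     chrom start   end category   name
#> 1:   chr1 50801 51700   repeat   L1_A
#> 2:   chr1 73001 73800   repeat   L1_A
#> 3:   chr1 84201 85100   repeat   L1_A
```

`k_a`/`k_b` are normalised weighted counts: the planted 8-fold element is
recovered as strongly enriched (its measured fold is compressed below 8
because position-based PCR-duplicate removal saturates over dense loci —
see the methods vignette), while the null family `B1_B` stays flat
(log2fc ≈ 0, adjusted p ≈ 0.8). All three multi-mapping copies are found
because each read's weight is spread across the identical copies rather
than discarded.

`run_pipeline(pipeline_config(...), outdir)` chains these stages (with
deduplication and a manifest of parameters, seeds and checksums) over a
validated configuration; `vignettes/repeat-aware-clip.Rmd` documents the
models, parameter defaults and design decisions.

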