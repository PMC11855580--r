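---
title: "Methods: BSA-seq mapping of pepper immature-fruit color"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-seq mapping of pepper immature-fruit color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbsa)
```

## The mapping problem

Immature pepper fruit color ranges continuously from yellow to deep green and
is driven by pericarp chlorophyll content. In a cross between a yellow-fruited
and a green-fruited parent, the F2 segregates across six visually scored color
grades, consistent with a small number of loci acting with dominance. Bulked
segregant analysis (BSA-seq) maps such loci by pooling DNA from the two
phenotypic extremes of the F2 — here 13 extreme-yellow and 20 extreme-green
plants — sequencing the pools alongside both parents, and scanning the genome
for sites where the two bulks' allele frequencies diverge.

`pepbsa` implements the analysis layer of that design: the variant-table
plumbing and parental-informativeness filter, the two scan statistics with
window aggregation and interval calling, coding-sequence consequence
annotation for the candidate genes, and the phenotype statistics. Because the
underlying reads are not redistributable, the package also ships a forward
simulator of the full design, so every stage can be exercised and verified
against known truth.

## Scan statistics

Only sites that are homozygous in both parents *and* differ between them are
informative: at such a site every F2 read can be assigned to a parent. The
filter calls a parent homozygous when its minor-allele read fraction is at
most `max_minor_fraction` (default 0.05) at total depth at least
`min_parent_depth` (default 10). The source data give no explicit depth
rules for this step, so both knobs are exposed; the defaults are ordinary
short-read practice.

**SNP/InDel-index.** At an informative site, a bulk's SNP-index is the
fraction of its reads carrying the designated reference parent's allele. The
package defaults to the yellow parent; the green-parent index is the
complement, and the scan statistic
$\Delta\mathrm{SNP} = |\mathrm{index}_{D1} - \mathrm{index}_{D2}|$
is invariant under the choice. Near a causal locus the yellow bulk approaches
index 1 while the green bulk, under dominance, retains heterozygotes and sits
near 1/3 — the configuration that yields the textbook
$\Delta = 1 - 1/3 = 2/3$ at a fully dominant locus. Sites with bulk depth
below `min_depth` (default 10) are masked rather than contributing noisy
ratios.

**Euclidean distance.** The ED statistic treats each bulk's reads as a
frequency vector over the four nucleotides (for indels, over the two abstract
ref/alt alleles) and takes the Euclidean distance between the two bulks'
vectors; it is squared (ED²) to sharpen strong signals. For a biallelic site
ED reduces to $\sqrt{2}\,|p_{D1} - p_{D2}|$, so its range is $[0, \sqrt 2]$
and ED² at most 2. ED needs no parental orientation, which makes it a useful
cross-check on the Δ-index scan; `run_scan()` reports the Jaccard overlap of
the two interval sets as a concordance measure.

## Windows, smoothing, thresholding

Per-site values are averaged in sliding windows of 3 Mb advancing by 300 kb,
anchored at position 1 of each chromosome and truncated at its end; windows
are half-open `[start, end)` intervals, so a site at exactly `start +
window_bp` belongs to the next window only. Windows with fewer than
`min_markers` unmasked sites (default 10, appropriate at simulation marker
density; at full genome density the same rule would be thousands) are flagged
ineligible and excluded from thresholding.

Window means are smoothed per chromosome by LOESS (tricube weights, degree 1,
span 0.1, one robustness iteration) before thresholding. Whether the original
analysis smoothed sites or windows is not recorded; both modes exist here
(`loess_smooth()` accepts either track), and window-level smoothing is the
default because it is what the thresholding consumes. Chromosomes with fewer
than `max(5, degree + 2)` points pass through unsmoothed with a warning.

The significance threshold is the 0.99 quantile (top 1%) of eligible window
values, computed genome-wide by default; values tied with the threshold are
significant. Overlapping or adjacent significant windows merge into maximal
candidate intervals.

**Threshold scale on the reduced genome.** The simulated genome is two 50 Mb
chromosomes (about 330 windows), each deliberately carrying one causal locus.
On a real ~3 Gb, 12-chromosome genome the top-1% rule admits on the order of
a hundred significant windows, and the ten-odd chromosomes without a color
locus supply the null distribution. On the reduced genome neither holds: a
genome-wide top-1% is ~3 windows and is captured entirely by the stronger
peak. The two-locus analyses in `analysis/` and the recovery tests therefore
call intervals with `per_chromosome = TRUE` and `quantile = 0.9`, which
restores the *count* of significant windows per carrier chromosome (~17 of
167) to the same order as the full-scale top-1% rule and yields interval
widths (~8 Mb) comparable to the 6–13 Mb intervals a full-scale scan
produces. Both knobs are plain arguments; the package defaults remain the
genome-wide top-1% rule, and the null-calibration analysis uses those
defaults.

## The forward simulator

The simulator is the package's study-design stand-in, not a fixture: all of
its stages are exported, tested operations.

* **Genome and map.** Two chromosomes of 50 Mb with 50 evenly spaced
  markers/Mb (~5,000 parental-informative markers; the real experiment had
  ~8.9 M, scaled down for tractable test times) and a uniform 2 cM/Mb map.
  Gametes from the uniformly heterozygous F1 get a Poisson number of
  crossovers with rate length$_{cM}$/100, placed uniformly, no interference —
  the Haldane model, whose map function is exported as
  `haldane_recombination_fraction()`.
* **Color model.** Two causal loci: a major GLK2-like locus on chr10 (weight
  0.7) and a minor APRR2-like locus on chr01 (weight 0.3), both with
  dominance $h = 0.6$ — heterozygotes show 60% of the homozygous-green
  effect, matching a trait described as dominant with additive modulation.
  The green score is the weighted dosage-effect sum plus Gaussian noise
  (`noise_sd = 0.08`). Grade cuts `c(0.02, 0.08, 0.265, 0.62, 0.94)` were
  fixed once at the quantiles of the resulting score mixture matching the
  observed grade proportions 16:12:54:149:159:33 of the 423-plant F2, giving
  a realistic middle-heavy six-grade histogram.
* **RGB readings.** `assign_rgb()` encodes the score into the green channel
  so that the greenness index 2G−R−B is affine and strictly increasing in
  the score before clipping — emulating image-derived phenotyping without
  modelling images.
* **Bulks and depths.** The yellow bulk is the 13 lowest-scoring plants, the
  green bulk the 20 highest (ties broken by plant id). Pooling assumes equal
  DNA contribution per plant: a bulk's allele frequency at a marker is its
  mean dosage/2; read depth is Poisson (mean 40) and allele counts binomial.
  Parents are emitted as pure homozygotes, so simulated tables pass the
  informativeness filter unchanged. No sequencing-error or genotyping-error
  model is included.
* **Seeds.** Every stochastic stage takes a seed; the pipeline derives stage
  seeds from a single top seed with `split_seed()` (a fixed congruential
  rule, always below $2^{31}$), so partial re-runs reproduce exactly.

What the simulator deliberately does not emulate: reference bias, mapping
artefacts, depth heterogeneity along the genome, indel-rich regions, or
segregation distortion. Passing recovery tests shows the statistics and the
calling logic are correct under the stated sampling model — not that every
real-data pathology is handled.

## Expected bulk frequencies under dominance

Two benchmark expectations anchor the simulator to the mapped cross. Under a
single fully dominant locus, the dominant-phenotype class of an F2 is 1 GG :
2 GY, so the recessive-parent (yellow) allele frequency among those plants is
exactly 1/3 (~33%); the simulator reproduces this to within sampling error.
And the extreme-yellow bulk, selected on phenotype, is nearly fixed for the
yellow-parent allele at the major locus, so its yellow-allele read fraction
at depth 40 exceeds 98%. The observed green-bulk frequency at a major locus
can fall below 1/3 when selection is on a quantitative score (the extreme
green tail enriches homozygotes beyond the dominant-class average); the
dominance and weight parameters are exposed for exploring this.

## CDS consequence annotation

Variant positions are 1-based offsets from the A of the start codon; the
affected codon is $\lceil pos/3 \rceil$ and the within-codon position
$((pos-1) \bmod 3) + 1$. This convention reconciles the APRR2-like call:
base 1428 is the third base of codon 476, TGG→TGA, truncating the protein to
475 of 586 residues (81.1% retained). Consequences are called by translating
the reference and alternate codons under the standard genetic code;
truncated length is `codon_index - 1` for stop-gained calls, and domain
overlap is a range check in amino-acid coordinates. Indels are reported as
`frameshift` at the first affected codon with no downstream stop scanning —
none of the candidate-gene variants require it.

The GLK2-like variant as printed (C→A at 247 bp, TCG→TAG, truncation to 81
aa of 313) is internally inconsistent under this convention: base 247 is the
*first* base of codon 83, a TCG→TAG change requires a second-base
substitution (base 248), and a stop at codon 83 retains 82, not 81,
residues. The annotator applies the single stated convention and the
analysis script reports the discrepancy rather than special-casing it.
Fixture CDSs are synthetic sequences engineered to carry the relevant codons
at the relevant positions (and labelled `_synthetic`); no proprietary
reference sequence is embedded.

## Phenotype statistics

* **Greenness.** `green_index()` is 2G−R−B on 0–255 channels; it may be
  negative and is invariant under a common shift of all three channels.
* **Chlorophyll.** For 95% ethanol extracts read at 649/665 nm:
  $C_a = 13.95\,D_{665} - 6.8\,D_{649}$,
  $C_b = 24.96\,D_{649} - 7.32\,D_{665}$ (mg/L), with the total both as
  $C_a + C_b$ and directly as $18.16\,D_{649} + 6.63\,D_{665}$ — identical
  because the combined coefficients are the exact sums. Negative outputs
  (absorbance pairs outside the model) are flagged. Content per gram fresh
  weight is $C \cdot V \cdot D / W$. `simulate_absorbance()` inverts the
  2×2 system at a chosen a:b ratio (default 3:1) so the round trip recovers
  a stated true content exactly at zero noise.
* **Normality report.** Mean, sample SD, *adjusted* Fisher–Pearson skewness
  G1 and adjusted excess kurtosis G2, and Shapiro–Wilk W/p via Royston's
  algorithm. The adjusted estimators are the ones that reproduce the
  published grade-count table to three decimals (the naive moment estimators
  do not); the report is computed over the six grade counts (n = 6), which
  is the published table's own basis. The published text and table disagree
  on the p-value (0.072 vs 0.72); the report prints the computed value
  (0.072) and leaves interpretation to the reader.
* **Association.** Genotype-by-grade tables are plain cross-tabulations with
  margins; segregation is tested by Pearson chi-square GOF against 1:2:1.
  The accession-panel 2×2 uses the odds ratio with the Haldane–Anscombe
  +0.5 correction applied only when a zero cell occurs, and a two-sided
  Fisher exact p as the primary inference. Heterozygous carriers in the
  panel are counted as mutation-present (the published convention is not
  stated; the contingency tables are inputs, so any other convention is a
  different input).

## Numerical choices and edge cases

Zero-depth or low-depth sites are masked (`NA`) and excluded from window
means rather than propagating NaN. Empty chromosomes emit no windows;
windows with no unmasked sites carry `NA` values and are ineligible.
Quantile thresholds use R's default type-7 quantile; ties at the threshold
are significant. Interval merging treats windows sharing a boundary
(half-open adjacency) as mergeable. Constant tracks smooth to themselves;
LOESS uses the direct surface so fitted values are exact, not interpolated.
All coordinates are 1-based inclusive in tables and half-open `[start, end)`
for windows and intervals; BED output converts to 0-based half-open.

## Problem sizes

The shipped analyses and tests run the simulator at 5,000 markers and 423
plants; recovery and null-calibration properties use 50 replicates each, and
the bulk-frequency benchmarks 20 replicates (n = 10,000 F2 plants for the
dominant-class frequency, at a sparse 10-marker map since only the causal
locus matters there). These sizes keep the full suite around a minute while
leaving the statistical checks comfortably powered.

## Limitations

The package does not call variants, lift genome coordinates into CDS
coordinates, or model transcriptome evidence; the scan consumes allele-depth
tables, and the annotator consumes CDS-relative variants. The Δ-index null
band used elsewhere in the QTL-seq literature (depth-dependent simulation
envelopes) is out of scope — thresholding is by the quantile rule the
original analysis used, with an explicit override for the "adjusted as
needed" case.
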