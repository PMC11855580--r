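# pepbsa

Bulked segregant analysis (BSA-seq) of immature pepper fruit color, as a
tested R package plus a scripted analysis workflow.

Immature fruit color in pepper (*Capsicum annuum*) runs from yellow to deep
green with pericarp chlorophyll content. In an F2 from a yellow × green
cross the trait segregates across six color grades under a major
(GLK2-like, chr10) and a minor (APRR2-like, chr01) locus with dominant and
additive effects. BSA-seq maps such loci by sequencing pooled DNA from the
phenotypic extremes (here 13 extreme-yellow and 20 extreme-green plants)
together with both parents and scanning for allele-frequency divergence
between the pools.

The package implements:

* **Variant tables** — a native TSV and VCF (AD-field) reader/writer for
  four-sample (P1, P2, D1, D2) allele-depth tables, and the
  parental-informativeness filter (homozygous in both parents, different
  between them).
* **Genome scan** — per-site SNP/InDel-index and ΔSNP-index
  (`|index_D1 − index_D2|`), the squared Euclidean-distance statistic over
  nucleotide-frequency vectors, 3 Mb / 300 kb sliding windows, LOESS
  smoothing, top-1% quantile thresholding and maximal-interval calling,
  with BED output.
* **F2 forward simulator** — Haldane-model gametes, a two-locus dominance
  color model binned into six grades, extreme-bulk selection and
  Poisson/binomial pooled read sampling; the verification harness for every
  scan property.
* **CDS consequence annotation** — stop-gained/missense/synonymous calls
  with codon arithmetic, truncated-protein lengths and domain overlap
  (e.g. a G→A at CDS position 1428 of a 586-codon gene → TGG→TGA,
  truncation to 475 aa).
* **Phenotype statistics** — the 2G−R−B greenness index, chlorophyll
  quantification from 649/665 nm absorbance, normality reports (adjusted
  G1/G2 moments + Shapiro–Wilk), genotype×grade tables, 1:2:1 segregation
  tests and accession-panel association (odds ratio + Fisher exact).

## Worked example

```r
library(pepbsa)

ds <- simulate_bsa_dataset(seed = 42)   # 423 plants, 5,000 markers
scan <- run_scan(ds$table, per_chromosome = TRUE, quantile = 0.9)
scan$intervals
#> # A tibble: 4 × 6
#>   chrom    start      end peak_value n_windows statistic
#>   <chr>    <dbl>    <dbl>      <dbl>     <int> <chr>
#> 1 chr01 22800001 30600001      0.871        17 delta_index
#> 2 chr10 20400001 28200001      0.952        17 delta_index
#> 3 chr01 22800001 30600001      1.52         17 ed2
#> 4 chr10 20400001 28200001      1.82         17 ed2
scan$jaccard
#> [1] 1
```

Both called ΔSNP-index intervals contain their simulated causal positions
(chr01:25,000,000 and chr10:25,000,000), the interval peak on chr10 (the
major locus) is higher than on chr01, and the ED² intervals coincide with
the Δ-index intervals (Jaccard 1), mirroring how the two statistics
corroborate each other on real data.

```r
normality_report(c(16, 12, 54, 149, 159, 33))
#> # A tibble: 1 × 7
#>       n  mean    sd skewness kurtosis     W p_value
#>   <int> <dbl> <dbl>    <dbl>    <dbl> <dbl>   <dbl>
#> 1     6  70.5  66.4    0.775    -1.87 0.810  0.0724
```

The six F2 color-grade counts (423 plants in total) give the grade
distribution's mean, SD, adjusted skewness/kurtosis and Shapiro–Wilk W.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cross, bulks, variant table, phenotypes
Rscript analysis/02_scan.R        # delta-index + ED^2 scan, intervals BED
Rscript analysis/03_effects.R     # candidate-gene CDS consequence calls
Rscript analysis/04_phenostats.R  # grade stats, genotype tables, association
```

Set `PEPBSA_SEED` to change the simulation seed (default 42).

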