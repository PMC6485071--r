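# popdiff

Selection scans from population differentiation, and divergence times
from relative cross-coalescence rates, for small cohorts pooled into a
handful of ancestry groups.

`popdiff` is aimed at population-genetics analyses where per-population
sample sizes are too small for frequency-spectrum or haplotype-based
selection statistics. It implements:

* **per-site pairwise F<sub>ST</sub>** between all group pairs, using the
  Hudson estimator with small-sample (n−1) corrections:

  F̂<sub>ST</sub> = [ (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) ] /
  [ p₁(1−p₂) + p₂(1−p₁) ]

* **the d statistic** per site and focal group i,

  d<sub>i</sub> = Σ<sub>j≠i</sub> (F<sub>ST</sub>(i,j) −
  E[F<sub>ST</sub>(i,j)])² / sd[F<sub>ST</sub>(i,j)],

  with empirical percentiles and top-0.1% outlier calls;
* **greedy LD clumping** of outliers into tag variants
  (p1 = 0.001, p2 = 0.01, 1000 kb, r² > 0.5) and **merged selection
  windows** (r² > 0.8 within 1 Mb of each tag);
* a **locus-local annotation-shift permutation test** (10,000
  permutations per category, Bonferroni family-wise control: 0.05/9
  categories = 5.56 × 10⁻³);
* **RCCR divergence times**: RCCR = 2λ<sub>cross</sub> /
  (λ<sub>within1</sub> + λ<sub>within2</sub>), with divergence defined by
  the first present-to-past upcrossing of 0.5 (0.25/0.75 bound the
  interval), and MSMC-style unit scaling μ = νg
  (ν = 4.3 × 10⁻¹⁰/year, g = 29 years ⇒ μ = 1.25 × 10⁻⁸/generation);
* **seeded synthetic data**: Balding–Nichols genotypes with planted
  frequency spike-ins, block-copy LD fixtures, and pairwise coalescence
  times under a clean two-deme split — ground truth for every stage.

Inputs are standard formats: VCF (biallelic SNP GT calls) plus a
sample→group TSV, BED annotation tracks, and whitespace-delimited
MSMC-style rate tables. Variant tables are 1-based (VCF convention);
interval outputs are 0-based half-open BED.

## Worked example

```r
library(popdiff)

## three groups of 25 diploids, 20,000 sites, 10 planted loci with a
## +0.4 frequency shift in group G1
sim <- simulateGenotypes(nGroups = 3, samplesPerGroup = 25,
                         nSites = 20000,
                         spike = spikeConfig(10, focalGroup = 1,
                                             freqShift = 0.4),
                         seed = 42)
gd <- sim$genotypes
gd
#> GenotypeData: 20000 sites x 75 samples
#>   groups: G1 (25), G2 (25), G3 (25)
#>   missing calls: 5.00%

keep <- missingnessFilter(gd)          # per-group 20% rule
attr(keep, "counts")
#>    input retained  dropped
#>    20000    19923       77

pf <- pairwiseFst(gd, sites = keep)
as.data.frame(pairSummaries(pf))[, c("mean", "sd", "nSites")]
#>             mean         sd nSites
#> G1:G2 0.01763531 0.05109267  19899
#> G1:G3 0.01780423 0.05057891  19898
#> G2:G3 0.01764709 0.05088944  19902

ds <- callOutliers(dStatistic(pf))     # top 0.1% per group
ds
#> DScanResult: 19923 sites x 3 groups
#>   outliers per group: G1=19, G2=19, G3=19

cl <- clumpOutliers(ds, "G1", gd)      # p1 0.001 / p2 0.01 / 1 Mb / r2 0.5
cl
#> ClumpResult for group G1
#>    20 clumps, 20 member variants
win <- selectionWindows(cl, gd)        # r2 > 0.8 within 1 Mb, merged
head(win, 3)
#> GRanges object with 3 ranges and 1 metadata column:
#>       seqnames    ranges strand |     nTags
#>   [1]        1    548000      * |         1
#>   [2]        1    731000      * |         1
#>   [3]        1   1249000      * |         1
```

The pair means sit near the configured background differentiation
(F = 0.02), each group flags ~0.1% of its defined sites as outliers, and
the clumps/windows mark the most differentiated loci in G1 — five of the
ten planted spikes make the genome-wide top 0.1% in this run (the
Balding–Nichols generator draws sites independently, so each clump here
is a single variant and isolated tags give 1-bp windows).

Divergence times from the clean-split coalescent simulator (split at
3000 generations, deme size 10,000):

```r
tt <- simulatePairCoalescence(Tsplit = 3000, Ndeme = 1e4, Nanc = 1e4,
                              nPairs = 1e5, seed = 42)
bins <- c(0, exp(seq(log(50), log(max(unlist(tt)) + 1),
                     length.out = 32)))
rcc <- computeRccr(ratesFromTimes(tt, bins), timeUnit = "generations")
crossingTimes(rcc)
#> DivergenceEstimate ( generations ): t25 = 2643.163 , t50 = 3062.096 ,
#> t75 = 3478.002
```

The 0.5-crossing lands close to the true 3000-generation split; at 29
years per generation the report line reads `~89 (77-100) kya`.

A thin command-line wrapper with `simulate`, `pipeline` and `rccr`
subcommands is installed at `inst/scripts/popdiff`; `runPipeline()` is
the same entry point from R and writes every stage table, the serialized
configuration, and a run manifest.

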