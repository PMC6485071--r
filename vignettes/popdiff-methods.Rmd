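---
title: "Differentiation scans and cross-coalescence divergence times with popdiff"
author: "popdiff maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiation scans and cross-coalescence divergence times with popdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`popdiff` implements a per-site population-differentiation selection scan
for small cohorts pooled into a handful of ancestry groups, together with
the coalescence-rate conventions needed to turn MSMC-style output into
divergence-time estimates. The pipeline is:

1. filter sites on per-group missingness;
2. per-site pairwise Hudson F~ST~ between all group pairs;
3. the *d* statistic per site and focal group, with empirical percentiles
   and top-0.1% outlier calls;
4. greedy LD clumping of outliers into tag variants;
5. merged selection windows around the tags;
6. a locus-local annotation-shift permutation test with Bonferroni
   family-wise control;
7. (independently) relative cross-coalescence rate (RCCR) curves and
   threshold-crossing divergence times.

A seeded synthetic-data module (Balding–Nichols genotypes with optional
frequency spike-ins; pairwise coalescence times under a clean two-deme
split) provides ground truth for every stage.

# The model and the statistics

## Per-site F~ST~

With alternate-allele frequencies $p_1, p_2$ estimated from $n_1, n_2$
called alleles, the per-site estimator is the Hudson form with unbiased
within-group heterozygosity:

$$
\hat F_{ST} \;=\;
\frac{(p_1-p_2)^2 \;-\; \frac{p_1(1-p_1)}{n_1-1} \;-\; \frac{p_2(1-p_2)}{n_2-1}}
     {p_1(1-p_2) + p_2(1-p_1)} .
$$

The $n-1$ corrections remove the sampling variance of the frequency
estimates, which matters at the cohort sizes this scan targets (tens of
alleles per group). Consequences we embrace rather than fight:

* per-site values can be **negative** (the noise floor at equal
  frequencies); they are retained, because the *d* statistic standardises
  each pair against its own genome-wide mean and standard deviation, and
  clipping would bias both moments;
* a site monomorphic and identical in both groups has a zero denominator
  and is **undefined** for that pair (excluded from that pair's moments);
* allele counts are the sufficient statistic: dropping missing calls
  changes $n$, never the estimator given the counts.

The scan is strictly per-site; no windowed or ratio-of-averages F~ST~ is
computed, because the *d* statistic consumes per-site values.

## The d statistic

For focal group $i$ at a site,

$$
d_i \;=\; \sum_{j \neq i}
\frac{\left(F_{ST}(i,j) - E[F_{ST}(i,j)]\right)^2}{\mathrm{sd}[F_{ST}(i,j)]},
$$

where the mean and standard deviation are taken over all retained sites
for that pair. Note the asymmetric form: the numerator is squared while
the denominator is the *unsquared* standard deviation. We implement this
form exactly as the canonical definition; because a symmetric,
fully-standardised variant is also in circulation, `dStatistic(squared =
FALSE)` offers the signed sum $\sum_j (F - E)/\mathrm{sd}$ for
comparison (default off). The squared form is non-negative and
dimensionally mixed (units of F~ST~); none of the downstream steps depend
on its scale, only on ranks.

A site's $d_i$ is undefined whenever any required pair is undefined
there — we drop per (site, group) rather than impute, and report the
counts. A pair with zero standard deviation aborts the focal group's scan
with a diagnostic: the statistic does not exist in that case and
silently skipping would hide a degenerate input.

## Outliers, percentiles, clumping, windows

* **Percentile** = percent of defined variants in the same group with a
  strictly higher *d*.
* **Outliers** = sites strictly above the empirical $(1-0.001)$ order
  statistic of the group's defined *d* values (top 0.1%). Ties exactly at
  the threshold are all excluded (conservative) and counted; fewer than
  1000 defined sites triggers a degenerate-threshold warning.
* **Clumping** follows the classic greedy rule with the scan's
  conventions: index candidates are variants with percentile fraction
  below `p1 = 0.001`, visited in decreasing *d* order (genomic position
  breaks ties, lower coordinate first); each unclaimed index claims all
  unclaimed variants with fraction below `p2 = 0.01`, within
  `windowKb = 1000` of the index and with $r^2 > 0.5$ to it. Distance is
  tag-to-member, not member-to-member. The tag is the index variant — by
  construction the clump member with the highest *d*.
* **Selection windows**: for each tag, the interval spanning all variants
  within 1 Mb and $r^2 > 0.8$ with it (an isolated tag gives a 1-bp
  window); overlapping windows are merged. The 0.8/1 Mb pass is run
  separately over the tags rather than reusing the clump memberships,
  matching the two-threshold description of the procedure.

$r^2$ is the squared Pearson correlation of genotype dosages over
pairwise-complete samples (composite LD). Haplotype-frequency
EM $r^2$ on unphased data is a deliberate non-goal; on the synthetic
fixtures the two agree closely, and all oracle tests target the dosage
definition.

## Annotation-shift enrichment

Each tag defines a locus: the tag plus its LD proxies ($r^2 > 0.8$ within
1 Mb), spanned and padded by 50 kb per side so the null has local
background to move in. The observed score is the number of loci with at
least one SNP inside the annotation track. Under each of 10,000
permutations, every locus's *local* (span-clipped) annotation intervals
are circularly shifted by an independent uniform offset, wrapping within
the span, and the score is recomputed — SNP positions and the genome-wide
annotation landscape stay fixed, so the test asks only whether SNPs sit
inside local annotations more often than chance placement would allow.

The empirical P value is
$P = \max\!\left(\#\{S_\text{perm} \ge S_\text{obs}\},\, 1\right)/n_\text{perm}$.
The published description counts permutations *higher* than observed, but
that convention can produce $P = 0$, which is impossible for a valid
permutation P; we therefore use the standard $\ge$ convention with a
$1/n_\text{perm}$ floor. A locus whose local annotation footprint is
empty, or fills its whole span, cannot change state under any shift; such
loci contribute their observed state to every permutation and are
counted in the result.

Significance is controlled family-wise by Bonferroni:
$\alpha / K$ for $K$ categories, i.e. $0.05/9 = 5.56\times10^{-3}$ for
the nine-category annotation panel (DHS promoters/enhancers/dyadic, CAGE
enhancers, exons, introns, 3'/5' UTRs, conserved elements). The package
ships no annotation data; categories are generic labelled BED tracks.

## RCCR and divergence times

From binned coalescence rates $\lambda_{00}, \lambda_{01}, \lambda_{11}$
(within deme 1, cross, within deme 2),

$$ \mathrm{RCCR} = \frac{2\,\lambda_{01}}{\lambda_{00} + \lambda_{11}}, $$

which is $\approx 1$ while the demes still behave as one ancestral
population and $\to 0$ after complete separation. Divergence is defined
as the time at which the RCCR, read from the present into the past,
first rises through 0.5; the 0.25 and 0.75 crossings bound the reported
interval, formatted `~t50 (t25–t75) kya` in ascending order. Numerical
conventions, chosen for determinism and documented rather than inferred:

* bin representative time = arithmetic midpoint of the boundaries (left
  boundary for an open-ended last bin);
* crossings are located by linear interpolation between representative
  times; only the **first** present-to-past upcrossing is reported and
  any further crossings of a non-monotone curve are counted in a message;
* a threshold is reported only when the most recent defined bin lies
  below it — populations that never diverged yield `NA`, never a
  fabricated time;
* RCCR values above 1 (estimation noise) are retained, not clipped.

MSMC-style scaled units convert as: years $= t_\text{scaled}/\nu$ and
$N_e = (1/\lambda)/(2\mu)$ with $\mu = \nu g$. The defaults are
$\nu = 4.3\times10^{-10}$ per site per year and $g = 29$ years, giving
$\mu = 1.25\times10^{-8}$ per generation (3 s.f.) and
$2\mu = 2.5\times10^{-8}$. One published description also labels
$4.3\times10^{-10}$ a *per-generation* rate; only the per-year reading is
consistent with $\mu = \nu g = 1.25\times10^{-8}$, so that is what the
package implements.

# The synthetic-data generators

## Balding–Nichols genotypes

Each site draws an ancestral frequency $p \sim U(0.05, 0.95)$; group $g$
draws its frequency from
$\mathrm{Beta}\!\left(p\,\tfrac{1-F_g}{F_g},\,(1-p)\,\tfrac{1-F_g}{F_g}\right)$
(mean $p$, variance $p(1-p)F_g$), and diploid genotypes are
$\mathrm{Binomial}(2, q_g)$ with independent per-call missingness.
Sites are independent — the generator has no linkage; LD fixtures are
built by `blockCopyVariants()`, which duplicates a site's genotype vector
with per-call reflection noise to create blocks of known $r^2$.

Defaults, chosen once as the package's study conditions:

* **6 groups × 25 diploids**: six pooled ancestry groups is the scan's
  intended use; 25 diploids per group is the canonical fixture scale used
  throughout the validation suite.
* **F = 0.02 per group**: typical genome-wide background differentiation
  between most pairs of closely related continental subpopulations.
  This value is also a *power design* choice: the planted-spike
  validation shifts a focal group's allele frequency by 0.4 at 20 sites,
  and a design-stage power analysis showed that against strong
  backgrounds (F around 0.1) the null *d* distribution's tail — driven by
  the heavy-tailed per-site estimator noise at ~50 alleles per group —
  swallows even that large an effect, while against the F = 0.02
  background the spiked loci separate. A generator whose planted effects
  are undetectable by construction would validate nothing, so the default
  background is the low-differentiation regime; spec-level conditions
  that state their own F (e.g. the two-group F~ST~ recovery run at
  F = 0.1) use it explicitly.
* **ancestral range (0.05, 0.95)**: avoids near-fixed sites, stabilising
  the per-pair F~ST~ moments the *d* statistic standardises against.
* **5% missingness**: exercises the missingness filter and the
  pairwise-complete $r^2$ without dominating the data.
* **spike mechanism**: additive frequency shift with clamping to [0, 1],
  applied before genotypes are drawn, so the planted effect size is
  interpretable on the frequency scale; the truth table records realised
  frequencies and spiked site ids.

A single user-facing seed fans out to fixed per-stage substreams, so
stages can be rerun independently and identical seeds reproduce output
bit-identically.

What the generator does *not* emulate: linkage and recombination,
ascertainment, allele-frequency-spectrum distortions from real
demography, sequencing error structure, or selection dynamics beyond the
frequency spike. Passing tests therefore certify the statistical
machinery, not robustness to every property of real data.

## Clean-split pair coalescence

A within-deme lineage pair waits $\mathrm{Exp}(1/2N_\text{deme})$; if the
time exceeds the split time $T$ it redraws from $T$ with rate
$1/2N_\text{anc}$. A cross-deme pair cannot coalesce before $T$ and then
waits with rate $1/2N_\text{anc}$. Binned rates are estimated as
coalescences over lineage-pair exposure with exact within-bin survival
accounting (a pair coalescing mid-bin contributes partial exposure),
which makes the estimator unbiased per bin; zero-exposure bins are
flagged undefined. `expectedRateCurveCleanSplit()` provides the
closed-form expected binned rates of the same model — the analytic
counterpart used to check the Monte-Carlo estimates and their RCCR
crossings.

# Validation design notes

Two of the statistical validation checks need care to be valid tests at
all; both are documented here because the naive versions look right and
are not.

* **Exchangeability of *d* across groups.** Comparing two groups' *d*
  values over the *same* sites with a two-sample KS test over-rejects:
  the two statistics share each site's focal-pair F~ST~ term, and each
  group's standardisation carries its own moment-estimation noise. The
  suite therefore estimates the pair moments genome-wide (as the scan
  does) and compares the groups on small *disjoint* site subsets, so the
  two KS samples are independent and the residual moment noise sits well
  below KS resolution.
* **Uniformity of permutation P values.** The reported
  $P = \max(\#\{\ge\},1)/n_\text{perm}$ is valid but super-uniform on a
  discrete score, so a KS test against $U(0,1)$ would reject by
  construction. The uniformity check instead forms the randomised
  p-value
  $\left(\#\{S_\text{perm} > S_\text{obs}\} + U\cdot(1 + \#\{S_\text{perm} = S_\text{obs}\})\right)/(n_\text{perm}+1)$
  from the stored permutation scores, which is exactly $U(0,1)$ under
  the exchangeable null (annotations placed uniformly and circularly
  within each locus span).

Problem sizes used by the validation suite and the acceptance script,
chosen as comfortable desk-scale runs: 50,000 sites × 2 groups for
F~ST~ recovery against a 400,000-draw Monte-Carlo oracle; 100,000 sites
× 6 groups for outlier calibration and spike power; ≤ 200-variant
fixtures for exact brute-force clump/window equivalence; 200 replicates
× 500 permutations for P-value uniformity; 100,000 lineage pairs per
category, 32 log-spaced time bins, for RCCR crossing recovery (split at
3000 generations, deme size 10,000).

# Limitations

* The scan's sensitivity depends strongly on background differentiation
  and per-group sample size; with ~25 diploids per group the per-site
  estimator noise is substantial, and only large frequency shifts are
  detectable as top-0.1% outliers.
* The exact small-sample F~ST~ estimator used by any particular published
  scan may differ in detail; results on real data are sensitive to that
  choice, which is why the estimator here is stated explicitly.
* Composite (dosage) $r^2$ differs from haplotype EM $r^2$ on unphased
  data; clump memberships near the threshold can differ accordingly.
* The RCCR machinery consumes rate tables; inferring those rates from
  sequence data (the MSMC HMM itself), phasing, and variant calling are
  out of scope.
* The shift-permutation locus definition (proxy $r^2$ threshold, 50 kb
  padding) is a declared default, not an inferred one; enrichment
  conclusions can move with it.
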