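---
title: "Methods: two-population sweep scans and deletion-trait association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population sweep scans and deletion-trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Livestock populations under long-term artificial selection — cashmere
goats selected for fiber traits are the motivating case — carry
*selective sweeps*: genomic intervals where a favoured variant dragged
linked variation to high frequency, leaving locally reduced nucleotide
diversity in the selected population and elevated differentiation
against unselected relatives. `sweepscan` implements the standard
two-population scan for such regions from a filtered SNP panel, the
confirmation statistics used to corroborate candidates, simple
individual-level population structure summaries (p-distance
neighbor-joining, LD decay), and the downstream candidate-variant
analyses: genotype frequency tables and a dosage-coded linear model
relating a structural (deletion) allele to a quantitative trait with
sex and batch covariates and an optional two-locus interaction.

Everything is exercised end to end on a synthetic two-population
generator, so the statistical behavior of the whole pipeline is
testable on a laptop without any sequencing data.

# The scan

## Statistics per window

Windows of `size` bp advance in `step` bp increments (defaults 150 kb
and 10 kb). Per window and population, nucleotide diversity is

$$\theta_\pi = \frac{1}{L}\sum_{\text{sites}} \frac{2 j (n - j)}{n (n - 1)},$$

with $j$ the alternate-allele count, $n$ the non-missing allele count
at the site and $L$ the window size in bp — the unbiased mean pairwise
difference per bp, matching the conventional `--window-pi` semantics.

Differentiation is the Weir & Cockerham (1984) two-population moment
estimator. Per site we compute the among-population component $a$ and
the total $a + b + c$ from the per-population sample sizes, allele
frequencies and observed heterozygote proportions (all from
non-missing calls); the window estimate is the *ratio of sums*
$\sum a / \sum (a+b+c)$ — the "weighted" estimator — never the mean of
per-site ratios, which is biased toward noisy low-information sites.
Negative estimates are retained: clamping at zero would distort the
genome-wide distribution that the Z-transform standardizes.

Tajima's D per window is
$D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}$ with the usual
constants $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ evaluated at a fixed
chromosome count $n$. Under missing data $n$ varies by site; the
constants assume it fixed, so each window uses the *minimum* per-site
non-missing allele count among its usable sites — a conservative
single-$n$ approximation. Windows with no segregating site, or fewer
than 4 chromosomes, report `NA`.

## Ranking and outlier calling

Window Fst values are Z-transformed over all retained windows
genome-wide (sample standard deviation, denominator $n-1$), and the
diversity contrast is $\log_2(\theta_{\pi,\text{focal}} /
\theta_{\pi,\text{reference}})$ — strongly negative where the focal
population lost diversity. Joint outliers are windows reaching the
$(1-q)$ quantile of ZFst *and* of $|\log_2\text{ratio}|$
simultaneously, with $q = 0.01$ by default; ranking on the absolute
ratio keeps the criterion two-sided. Quantiles use linear
interpolation between order statistics (R's type 7), pinned for
reproducibility, and threshold ties are included (≥). The thresholds
are always recomputed from the data at hand and reported in the call
set, so the analog of a printed cutoff such as "ZFst > 4.01" is a
property of each dataset, not a constant of the package.

Windows with fewer than `min_snps` SNPs (default 10 — a policy choice,
exposed in `window_spec()`, since scan tools are typically silent on
this rule) or with no usable Fst site are flagged `BELOW_MIN_SNPS`,
excluded from standardization and ranking. A window where either
population's diversity is exactly zero has no log ratio and is flagged
`RATIO_UNDEFINED`; flag removal happens *before* the two top-1% sets
are formed, and the retained count is recorded in the call set.

Adjacent or overlapping outlier windows (gap ≤ the scan step) merge
into sweep *regions*; genes whose interval, extended by a 500-kb flank
on each side, intersects a region are its candidates. The fine-scale
confirmation profile recomputes all statistics on nonoverlapping
10-kb windows genome-wide, Z-standardizing over that fine-window
distribution (scale-consistent, rather than reusing the 150-kb
standardization) and returns the region's rows.

# The generator

`sim_config()` defines the study conditions; `simulate_dataset()` is a
pure function of the config (including its seed — a single seeded R
RNG with a documented call order: ancestral frequencies, positions,
background frequencies, sweep redraw, genotypes, missingness, sex,
batch, residuals).

* **Background structure.** Ancestral frequencies are
  Uniform(0.05, 0.95) — informative loci that survive the MAF filter;
  site-frequency-spectrum realism is not a goal. Each population's
  frequency is Balding–Nichols:
  $p_k \sim \mathrm{Beta}(p\,(1-F)/F,\ (1-p)(1-F)/F)$, mean $p$,
  variance $p(1-p)F$, independently per population, with
  $F = 0.10$ by default. Two populations drawn this way yield a
  genome-wide weighted Weir–Cockerham Fst close to $F$ (the package's
  calibration check expects 0.07–0.13 at 20,000 SNPs and 50+50
  individuals).
* **The sweep** is emulated at the allele-frequency level, not by
  forward simulation: inside the region the swept population's
  frequency is redrawn with a much larger differentiation
  ($F_\text{sweep} = 0.6$) and pushed toward the nearer of 0 or 1 by a
  fixation factor (0.9), collapsing expected heterozygosity locally
  (≥5-fold under the defaults) while inflating differentiation — the
  pattern the scan consumes. The default sweep spans **300 kb on a
  10-Mb contig** (positions 4,850,001–5,150,000). The extent is
  deliberately *twice the window size and about 2% of all windows*: a
  top-1% outlier scan is only a coherent recovery test when the
  planted anomaly is a small fraction of the genome, as real sweeps
  are; a multi-megabase sweep on a 10-Mb test contig would occupy far
  more windows than the quantile can flag and the genome-wide
  Z-standardization would no longer describe a "background".
* **Genotypes** are Binomial(2, $p_k$) per individual (Hardy–Weinberg
  within population), with cells knocked out to missing independently
  (2% by default).
* **Deletion loci** are biallelic records (`<DEL>` alternate allele)
  with fixed per-population frequencies (0.80/0.10 at the in-sweep
  locus, 0.60/0.20 at a distal locus) and additive trait effects.
  The trait is
  $y = b_0 + \sum_k b_k g_k + b_{12} g_1 g_2 + \beta_\text{sex}
  \mathbf{1}[\text{male}] + \beta_\text{batch} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, with $b_0 = 15$, $b_k = 0.3$
  trait units per deletion copy, $\beta_\text{sex} = 0.5$, two batches
  (0 and 0.3), $\sigma = 1$ and no interaction unless configured. The
  per-copy effects are placeholders sized for recovery testing
  (roughly $0.3\sigma$), not estimates of any real deletion's effect.
  Sexes and batches are assigned randomly and balanced (50/50, two
  batches), mirroring a two-recorder phenotyping design.
* **Fixture genes.** Three annotation intervals are written with every
  dataset: one inside the sweep, one 250–300 kb beyond its end
  (within the 500-kb flank) and one 800–850 kb beyond (outside it),
  so the flank rule is checkable end to end.

What the generator does *not* emulate: linkage disequilibrium among
background SNPs (sites are exchangeable draws, so LD decay on
simulated data shows only the $\approx 1/n$ sampling floor, no
distance trend), recombination maps, demography, genotyping error
structure beyond uniform missingness, and ascertainment. Passing
recovery tests therefore demonstrates the statistical machinery, not
performance under realistic haplotype structure.

# Association model

`associate_variant()` fits $y \sim \text{dosage} + \text{sex} +
\text{batch}$ by ordinary least squares on complete cases (no
imputation), with dosage the 0/1/2 copy count of the deletion allele —
additive coding only. Categorical covariates are one-hot encoded
against a first-level reference; a covariate that is constant in the
analyzed subset (an all-female panel, say) is dropped with a note
rather than failing. Standard errors come from
$s^2 (X^\top X)^{-1}$ with $s^2 = \text{SSE}/(n - \text{rank}(X))$ and
two-sided Student-t p-values. `interaction_association()` adds the
second locus and the product term and reports the latter. The response
is analyzed on the raw scale by default; a natural-log option exists
for right-skewed traits, offered without endorsement.

Numerical policies: a rank-deficient design is an error naming the
collinear columns (silent dropping hides real confounding); an exact
fit reports `SE = 0`, `p = 0` with a `PERFECT_FIT` flag instead of
NaNs, keeping downstream handling deterministic.

# Distances and trees

The p-distance between individuals is the mean over
pairwise-complete sites of $|g_i - g_j|/2$. Het-vs-het contributes 0
under this convention; because distance tools differ here, a
`het_het = "half"` option scores it 0.5 instead. Pairs sharing no
called site are an error naming the pair. Neighbor joining follows
Saitou–Nei exactly — join the pair minimizing
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$ — with two pinned policies: exact
ties in $Q$ break toward the lexicographically smallest label pair
(internal nodes inherit their clade's smallest leaf label), and
negative branch lengths are clamped to 0 without redistribution. On
additive matrices the reconstruction is exact to numerical precision.
Newick output prints branch lengths at 6 significant digits and quotes
labels containing metacharacters.

# Problem sizes and runtime

The package's own validation runs at the default study conditions:
20,000 SNPs on 10 Mb, 50+50 individuals, 986 overlapping 150-kb
windows, 20 replicate genomes for sweep recovery; 2,000 null
replicates at $n = 200$ for type-I calibration of the dosage and
interaction terms; 200 replicates each for effect recovery at
$n = 500$ ($b = 0.3$) and $n = 800$ ($b_{12} = 0.4$). These sizes give
binomial standard errors of about 0.5% on a 5% rejection rate and
1.5% on 95% coverage, which is the resolution at which the
calibration claims are made. A full suite run takes on the order of a
minute; single scans are seconds.

# Known limitations

* Two populations only; no multi-population Fst, no haplotype
  statistics (iHS, XP-EHH), no phasing.
* The Tajima's D minimum-$n$ policy is conservative when missingness
  is very uneven across sites in a window.
* LD decay is the unphased genotype-correlation surrogate for
  haplotype $r^2$; on the generator's independent loci it has no
  distance trend by construction.
* The window-level Fst Z-scores inherit the overlap correlation of
  sliding windows; inferential statements about trends should use
  nonoverlapping windows, as the package's own checks do.
* OLS association assumes independent residuals: no kinship or mixed
  model, appropriate for the two-candidate-locus design, not for
  genome-wide association.
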