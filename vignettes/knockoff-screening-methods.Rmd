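---
title: "Methods: window-based knockoff screening of sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based knockoff screening of sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kscreen)
```

## The problem

Whole-genome sequencing yields millions of variants, most of them rare,
with no natural testing unit outside genes. Conventional screens slide
windows across the genome, test each window, and apply Bonferroni or
Benjamini-Hochberg corrections. Bonferroni is severely conservative at
this scale; BH does not control the false discovery rate under the strong
local correlation (linkage disequilibrium, LD) of genotypes; and both tend
to flag *proxy* windows that are merely correlated with a causal variant.

`kscreen` implements a model-X knockoff screen. For each individual a
synthetic genotype vector is generated that preserves the LD structure of
the real data but is conditionally independent of the trait — a
genome-wide negative control. Every candidate window is tested in the real
cohort and in `M` synthetic cohorts with the *same* test ensemble, and a
selection filter on the contrast between real and synthetic importance
scores controls the FDR at a user-chosen target under arbitrary
correlation.

## The sequential knockoff generator

Genotype dosages `G` (n individuals x p variants) are processed in
genomic-position order. For variant `j` the generator:

1. conditions on its K-nearest LD neighbors `B_j`: variants within
   +/-100 kb with `|r| > 0.05`, strongest first, capped at
   `K = floor(n^(1/3))` (the cap keeps the per-variant regression stable
   as n grows; the +/-100 kb horizon reflects that LD is local);
2. fits the least-squares conditional mean of `G_j` on the original
   neighbors and on all `M` previously generated knockoff copies of those
   neighbors (per-copy coefficients), via the normal equations with a
   Cholesky solve and a tiny (1e-6) ridge fallback for rank-deficient
   designs;
3. forms each knockoff copy as fitted value plus an independently
   permuted residual vector.

Permuting residuals (rather than sampling a parametric error) is what
makes the construction usable for rare variants, whose dosage
distribution is zero-inflated and badly approximated by a Gaussian. The
knockoff dosages are continuous and deliberately never clipped to
`[0, 2]`; the marginal mean and variance of every column are preserved
exactly.

**Tightly linked variants.** Variants are first grouped by single-linkage
hierarchical clustering on `1 - |r|`, cut so that no cross-cluster pair
has `|r| > 0.75` (single linkage is the linkage that guarantees exactly
this property at the cut). Cluster co-members are excluded from each
other's conditioning sets and the whole cluster is generated jointly with
a shared permutation per copy, so the residual correlation inside the
cluster is preserved. Without this, the knockoff of a variant in
near-perfect LD would be an almost exact copy of the original and the pair
could never be detected; with it, the cluster acts as one discovery unit.
A consequence is that within-cluster *cross* pairs
(`cor(G_j, knockoff of G_k)`, j and k in one cluster) are intentionally
decoupled; exchangeability diagnostics should therefore be read across
clusters, not inside them.

The generator costs `O(np)`: one local correlation block, one clustering
pass and one small regression per variant. Same seed, same knockoffs,
bit for bit.

## The window test ensemble

Candidate windows of 1 bp, 1 kb, 5 kb and 10 kb tile each chromosome with
half-window overlap; the grid is anchored at a multiple of the half-width
at or below the first variant, so membership does not depend on where the
loaded region starts. 1 bp windows are emitted only at common
(MAF > 0.05) and low-frequency (0.01 < MAF <= 0.05) variant positions.

Each multi-bp window is scored by a Cauchy (ACAT) combination of:

* burden and dispersion (SKAT) tests of common + low-frequency variants,
  Beta(1, 25) MAF weights;
* burden and SKAT of rare variants (MAF <= 0.01, MAC >= 5), same weights;
* the same pair re-weighted by each supplied functional annotation score
  (min-max scaled to `[0, 1]` within the window, multiplied with the Beta
  weight; the scores are opaque numerics, e.g. CADD);
* an unweighted carrier burden of ultra-rare variants (MAC < 5) — the
  matching quadratic form is near-degenerate at such counts and is
  omitted;
* single-variant score tests for every variant in the window.

Components with no qualifying variants are omitted rather than entered as
p = 1, so sparse windows are not diluted. The identical code path scores
the original matrix and every knockoff copy; knockoff columns inherit the
original variants' categories and weights so the ensembles are matched.

Numerical choices worth knowing:

* **SKAT tail.** The mixture-of-chi-squares tail is computed by exact
  numerical inversion of the characteristic function (uniform-step
  midpoint sum with an aliasing-controlled step and an
  integration-by-parts tail correction, self-validated by successive
  refinement to ~1e-7 absolute / 0.2% relative); a Lugannani-Rice
  saddlepoint takes over below p = 1e-6 where the inversion loses digits
  to cancellation, and Liu moment matching is the last-resort fallback.
* **Saddlepoint for binary traits.** All single-variant and burden score
  tests of binary traits use the saddlepoint tail of the Bernoulli score
  CGF once the standardized score exceeds 2 (the normal tail below
  that). The CGF arithmetic is overflow-stable up to the attainable score
  supremum, with the boundary case (every carrier a case) evaluated
  exactly, and a half-lattice continuity correction is applied when the
  carrier count is small. This departs from restricting the correction to
  single-variant tests: without it the normal tail is both anticalibrated
  for rare variants and *asymmetric* between the discrete original
  dosages and the continuous knockoff dosages, which corrupts the
  original-vs-knockoff contrast precisely where the screen must be
  reliable.
* p-values are floored at 1e-300; ACAT inputs at `1 - 1e-15` from above
  and via the `1/(p*pi)` asymptote below 1e-15.

## The multiple-knockoff filter and Q-values

With importance scores `T = -log10 p` for the original and `T^1..T^M` for
the knockoff copies, each window gets

* `kappa`: which of the M+1 scores is largest (0 = original; ties go to
  the original),
* `tau`: that maximum minus the *median* of the remaining M scores,
* `W = (T - median(T^1..T^M)) * 1{T >= max(T^m)}`.

The selection threshold is the smallest `t` among the observed positive
`tau` of `kappa = 0` windows with

```
(1/M + (1/M) #{kappa >= 1, tau >= t}) / max(1, #{kappa = 0, tau >= t}) <= q
```

and the screen reports all windows with `kappa = 0, tau >= t`. At `M = 1`
this is exactly the classical knockoff filter on `W`. The numerator's
`1/M` offset is the multiple-knockoff gain: a single knockoff cannot
select anything unless at least `1/q` windows carry positive statistics
(10 at q = 0.1), while `M` knockoffs lower that detection threshold to
`1/(Mq)`. Using the median rather than the maximum of the knockoff scores
makes `tau` far less variable across knockoff redraws, which is what the
stability design quantifies.

The knockoff Q-value of a window is the smallest target FDR at which it
would be selected; selecting `{qvalue <= q}` and running the filter at
`q` are provably the same operation, and the test suite asserts this
duality on random inputs. All window sizes are pooled into a single
genome-wide filter pass.

## The synthetic-data generator

`simulate_genotypes()` draws haplotypes from a latent block-AR(1)
Gaussian copula thresholded at target allele frequencies and sums two
haplotypes into dosages. Defaults: blocks of 4-14 variants, latent
correlation 0.4-0.98, and a frequency-class mixture (35% common, 15%
low-frequency, 30% rare log-uniform down to MAC 5, 20% ultra-rare at
MAC 1-4) chosen to mimic the site-frequency spectrum of a sequencing
panel of a few thousand genomes. What it reproduces: blocky local LD,
occasional tight (`|r| > 0.75`) pairs, a heavy rare tail. What it does
not: recombination-rate variation, population-specific haplotype
backgrounds, long-range LD, and the near-complete nesting of rare
variants on single haplotype backgrounds seen in real data. Passing the
simulation suites therefore demonstrates correctness of the machinery
under realistic local LD, not performance on any particular cohort.

`simulate_phenotype()` implements the standard recipes: quantitative
`Y = X1 + sum(beta_j g_j) + eps` with `X1 ~ N(0,1)`, `eps ~ N(0,3)`;
binary traits through a logistic model whose intercept is solved
numerically so the cohort prevalence hits its target (10% by default).
Effect sizes follow either `beta_j = a / sqrt(2 m_j (1 - m_j))` with `a`
calibrated so the realized genetic variance `sum beta_j^2 var(g_j)` hits
its target *exactly* (0.05 for common-variant scenarios, 0.1 for rare),
or `beta_j = a |log10 m_j|` with `a` given (1.4 for the prioritization
and shadow designs, 0.7 for the stability design).

## Simulation designs and their scale

The `design_*` functions reproduce the package's experiments at sizes a
single CPU handles comfortably; the vignette states those sizes as the
package's study conditions.

* **Single region** (`design_single_region`): 200 kb panels, n = 5000,
  300 variants kept after replacing each tight-LD cluster by one random
  representative (so window-level FDR is well defined), 0.5% of variants
  causal inside one 10 kb window, M = 5, targets q in {0.05, 0.1, 0.2}.
  The same panel and knockoff set serve the common- and rare-variant
  scenarios, since knockoffs do not depend on the phenotype.
* **Genome-wide** (`design_genome_wide`): 10 causal + 50 noise loci of
  200 kb on separate chromosomes, 24 variants each, n = 3000, per-locus
  genetic variance 1, locus-level FDP at +/-50/75/100 kb buffers. At this
  scale a causal window holds only a couple of variants, so causal
  eligibility is restricted to MAF > 0.01: concentrating variance 1 on a
  near-singleton would hand single carriers ~15-SD outcome shifts and
  create chance carrier-sharing associations across loci that no local-LD
  knockoff can silence (non-local dependence is a stated limitation of
  the generator).
* **Prioritization and shadow** (`design_prioritization`,
  `design_shadow`): n = 3000 panels with long, tight LD blocks (latent
  rho 0.9-0.995) emulating a strong-LD region such as the APOE
  neighborhood, 0.25% causal in a 5 kb window, binary trait,
  `1.4 |log10 m|` effects. The shadow design makes the causal variants
  common and screens rare variants only, so every detection is a shadow
  false positive; knockoffs for the rare subset are generated from the
  full panel so they retain their LD with the excluded common causal
  variants — this is what lets the filter recognize the shadow. Under
  moderate generic LD the shadow effect is too weak for any method to
  detect at this scale, which is why these two designs use the tight-LD
  panel.
* **Stratification** (`design_stratification`): three subpopulations with
  Balding-Nichols allele-frequency drift (Fst 0.05) and a group-level
  trait shift (or, in the rare-driven mode, background rare-variant loci
  scaled by gamma); ancestry adjustment uses the leading 10 principal
  components of a separate 800-variant background panel, standing in for
  genome-wide PCA (PCs of one small test region are far too noisy to
  capture ancestry, and the adjusted comparison would measure PC
  estimation error rather than the screen).
* **Stability** (`design_stability`): one fixed dataset, a pool of
  knockoffs, repeated draws of M = 5; compares the variance of `tau` and
  the re-selection frequency of causal windows between the median-based
  and max-based statistics.

## Worked example

```{r example, eval = FALSE}
panel <- simulate_genotypes(n = 2000, p = 150, seed = 1)
sim <- simulate_phenotype(panel, sim_config(
  causal_fraction = 0.02, effect = "variance", variance_target = 0.4,
  family = "gaussian", focus = "common"
))
scan <- ks_scan(panel, sim$pheno, outcome = "y", covariates = "x1",
                family = "gaussian", M = 5, fdr = 0.1, seed = 2)
glance(scan)
dplyr::filter(tidy(scan), selected)
autoplot(scan)
```

## Known limitations

* The generator assumes one homogeneous LD structure across individuals;
  heterogeneous LD across ancestries and long-range dependence are not
  modeled, so population structure must still be adjusted for through
  covariates (the stratification design quantifies the residual
  behavior).
* Exchangeability is enforced locally (+/-100 kb, `|r| > 0.05`); cross-
  chromosome or long-range dependence — including chance carrier sharing
  among ultra-rare variants — is invisible to the generator.
* Relatedness is not modeled (no mixed-model adjustment).
* FDR control with overlapping windows is supported empirically by the
  simulation designs; the formal guarantee covers non-overlapping
  windows.
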