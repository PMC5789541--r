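---
title: "Methods: host genetic structure and the microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host genetic structure and the microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microgwas` implements an analysis pipeline for cohorts in which donors
have both host genotypes and microbiome profiles at one or more body
sites. This vignette is the package's account of the statistics it
computes, the choices behind them, and what the simulation-based tests do
and do not establish.

## The questions and the models

The pipeline addresses four linked questions.

**Does high-level genetic structure covary with community composition?**
Host population structure is summarized by principal components of the
common-variant dosage matrix. For each (log-transformed) microbial
feature $y_f$ we fit

$$ y_f = \beta_0 + \sum_{j=1}^{5} \beta_j \mathrm{PC}_j + \varepsilon $$

and record the coefficient of determination $R^2_f = 1 - SS_{res}/SS_{tot}$.
Because microbial abundances are zero-inflated, compositional and heavy
tailed, no parametric null is trusted: instead the donor labels are
shuffled $B$ times (default $B = 10{,}000$) and every statistic is
referred to its permutation distribution. One *shared* donor shuffle is
applied to all features per permutation — this preserves the inter-feature
correlation structure, which is what makes the *site-level* statistic
(the mean $R^2$ over features) exchangeable under the null. Per feature,
the empirical p-value is the add-one tail proportion
$p = (1 + \#\{b : R^2_{perm,b} \ge R^2_{obs}\})/(B+1)$, bounded below by
$1/(B+1)$; ties count as exceedances (conservative). The site summary is
a Z-score of the observed mean $R^2$ against the permuted means, plus an
empirical p of the same add-one form. Benjamini–Hochberg q-values are
attached across features.

**Which functional classes drive a ranking?** Pathways ranked by
decreasing $R^2$ are screened per superclass with the Beta
order-statistic (robust rank aggregation) score: with normalized member
ranks $r_{(1)} \le \dots \le r_{(k)}$ among $n$ features,
$\rho = \min_j P\big(\mathrm{Beta}(j, k-j+1) \le r_{(j)}\big)$ and
$p = \min(1, k\rho)$. The construction asks whether *some* prefix of the
class sits implausibly high, and the $k$-fold correction makes the score
super-uniform under random rankings (verified by simulation in the test
suite). A Wilcoxon rank-sum alternative (`method = "wilcoxon"`) is kept
for sensitivity analysis.

**Are cryptic relatives detectable, and do they share microbiota?**
Pairwise kinship uses the robust (KING-style) estimator

$$ \phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}} $$

from heterozygote-sharing and opposite-homozygote counts over jointly
non-missing sites. The sum-denominator form is used because its
expectation equals the kinship coefficient for non-inbred pairs and it
returns exactly 0.5 for duplicate genotypes; the min-denominator variant
published alongside it would differ for pairs with unequal heterozygosity,
and that deviation risk is accepted deliberately. Degrees follow the
standard half-open intervals (0.0442 / 0.0884 / 0.177 / 0.354); the
boundary value 0.354 itself, unassigned by the published ranges, goes to
`twin` (a measure-zero case). Community similarity between donor pairs is
$1 - BC$ with the Bray–Curtis dissimilarity computed on raw relative
abundances over *all* profiled species (before any prevalence filter):
the distance is meant to describe whole communities, not the
model-ready feature subset. Relative pairs are then compared against all
other pairs pooled with a two-sample t-test (pooled variance by default,
Welch behind a flag). Pairwise similarities are not independent
observations; the t-test is reported as the field's convention and should
be read descriptively — a permutation test respecting pair dependence is
out of scope and noted as a limitation.

**Do single variants associate with single taxa?** Targeted tests encode
a candidate variant additively (dosage 0/1/2) or recessively (indicator
of homozygous-alternate) and either regress each feature on it or compare
the two encoded groups by t-test, with BH correction across the screen.
The genome-wide scan fits, for every (variant, feature) pair, an ordinary
linear model with sex, ethnicity and collection-site covariates (one-hot,
first-level reference). It is computed by residualizing $y$ and $g$ on
the covariate design and converting the residual correlation to
$t = r\sqrt{df/(1-r^2)}$, $df = n - \mathrm{rank}(design) - 1$ — exactly
the OLS coefficient test, vectorized over features and variants (the
Matrix-eQTL computation). Scan hygiene: variants need MAF > 0.1 on the
analysis donors; the exact test count feeds `bonferroni_threshold()`;
per-feature hits are clumped by a greedy 10-kb positional rule (gap of
exactly 10,000 bp joins) with the minimum-p member as representative;
representatives are annotated with genes within 50 kb; `qq_points()`
diagnoses calibration.

## Feature preparation

Order of operations is fixed and deliberate: **average replicates →
prevalence filter → log transform**. Averaging is an arithmetic mean on
the raw relative-abundance scale (averaging after a log transform would
be a geometric mean, a different estimand), so it must come first;
prevalence is then assessed at the donor level. A sample-level prevalence
screen remains possible by calling `prevalence_filter()` before
`average_replicates()`.

Species are kept if present (abundance strictly > 0; profiles are assumed
already detection-thresholded upstream) in *at least* 25% of donors
(non-strict), then transformed as $\log_{10}(x + 10^{-5})$ — the
pseudocount is one order of magnitude below typical profiler detection
limits, and zero maps to $-5$. Pathways are kept if present in *more
than* 75% of donors (strict), and transformed as $\log_{10}(x)$ on
present values only, zeros becoming missing and dropped feature-wise from
model fits; pathway absence is rare enough that modelling it adds little,
and the reads-per-million scale has no natural pseudocount.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
any external download, and its defaults are the study conditions the
pipeline is meant for: 298 donors, four ancestral populations with
weights (0.73, 0.06, 0.09, 0.12), divergence $F_{st} = 0.1$
(continental scale), 11 planted first-degree pairs and one third-degree
pair, 119 species and 400 pathway features, one body site.

Genotypes follow the Balding–Nichols model — ancestral frequency
$p_0 \sim U(0.05, 0.95)$ per variant, population frequency
$\sim \mathrm{Beta}(p_0(1-F)/F, (1-p_0)(1-F)/F)$, dosage
$\sim \mathrm{Bin}(2, p_{pop})$ — chosen as the minimal model with
closed-form $F_{st}$ control. Related pairs are drawn by explicit
Mendelian transmission through minimal pedigrees (duplicate, parent–
offspring, shared-mother half-sibs, four-founder first cousins) using the
largest population's frequencies. Variant positions are placed uniformly
along one 50-Mb synthetic chromosome, enough to exercise 10-kb clumping
and 50-kb annotation without a real genetic map.

Microbiome profiles are zero-inflated log-normals: per feature a latent
$\log_{10}$ abundance (baseline $\mu_f \sim U(-4,-1)$ for species in
relative-abundance units, $U(1,4)$ for pathways in reads-per-million
units; donor noise $\sigma_f = 1$) plus any planted effects; replicate
samples add within-donor noise $\sigma_{rep} = 0.1$ ($\sigma_{rep} <
\sigma_f$; within-donor replicate variance is a free parameter with no
reference value, and 0.1 log units keeps replicates recognizably the same
donor). Entries are zeroed independently with per-feature presence
probability drawn from `prevalence_range` (default $U(0.25, 0.95)$), or a
constant `zero_inflation` if supplied; species rows are then renormalized
to sum to one, pathways stay on the reads-per-million scale. The
log-normal-plus-zero-mask construction was chosen over a multinomial read
model because the analysis operates on $\log_{10}$ abundances — planting
effects on the same scale the tests use makes planted slopes
interpretable as effect sizes.

Planted effects are linear on the latent scale: PC effects multiply
*standardized* PC scores (so a slope of 1 means one log10 unit per PC
standard deviation), variant effects multiply the encoded genotype. Two
constructions keep planted experiments meaningful: variants named in
`planted_variant_effects` draw their ancestral frequency from
$U(0.3, 0.7)$, emulating the common candidate variants such analyses
target and guaranteeing the planted variant survives the scan's MAF
filter; and planted features take the low end of the baseline range so
that a large log-scale effect does not make the feature dominate the
composition — under closure a dominant feature's effect leaks, inverted,
into every other feature's relative abundance, which would make "which
feature carries the signal" ill-posed.

One global seed expands into fixed per-stage child seeds
(genotypes, pedigree, species, pathways, metadata), so each stage is
independently reproducible and a full cohort is bit-identical across
calls.

What the generator does *not* emulate: linkage disequilibrium beyond
pedigree sharing, read-level noise, body-site-specific ecologies,
taxon–taxon interactions, or family-shared environment. Passing tests
therefore establish that the estimators are correct and calibrated under
a faithful statistical caricature of the data — not that real-data effect
sizes or discovery counts will reproduce.

## Numerical choices

- PCA standardizes each variant column by $2\hat p$ and
  $\sqrt{2\hat p(1-\hat p)}$ (unit HWE variance), mean-imputes missing
  dosages per variant (the PLINK convention), drops monomorphic and
  all-missing columns, and fixes component signs by requiring each
  loading vector to have a nonnegative sum — output is deterministic
  across BLAS implementations up to that convention. `k` above the matrix
  rank is an error, as is an input with no variation.
- The kinship denominator can be zero (no heterozygous sites); $\phi$ is
  then undefined and flagged rather than coerced.
- `linear_assoc` treats a genotype that is constant after complete-case
  deletion as "skipped with reason", but a genotype collinear with the
  covariates as an error (the model is misspecified, not merely
  uninformative). Residual correlations are clamped to $[-1, 1]$ before
  the t-transform to absorb floating-point overshoot.
- Clump ties (equal minimum p in a group) resolve to the smaller
  position; enrichment rank ties are pre-broken by feature name. Both are
  determinism guarantees, not statistical statements.
- Empirical p-values use the add-one form everywhere (per feature and per
  site): a plain proportion can return 0, which is impossible for a
  permutation p-value and breaks downstream $-\log_{10}$ handling. The
  floor at $B = 10{,}000$ is $1/10{,}001 \approx 0.0001$.

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the whole battery completes in
well under a minute of compute per file: kinship recovery uses 10,000
variants with 20–100 pairs per degree; null calibration uses 200 donors
× 200 features at $B = 500$; power checks use 20 seeded replicates of
200-donor cohorts (20 features for the PC effect at $B = 500$; 200
variants × 10 features for the scan). The estimator-level oracles
(OLS equivalence, eigendecomposition, contingency-table kinship,
exhaustive clump partition) run on instances small enough to verify by
brute force.

## Known limitations

Pairwise-similarity t-tests ignore pair dependence (see above). The scan
assumes complete cases per (variant, feature) pair, the behavior least
surprising for missing genotypes but wasteful if missingness is heavy.
No LD pruning, haplotype phasing, IBD segments, inbreeding coefficients,
rarefaction, CLR/ILR transforms or phylogeny-aware distances are
provided; they are out of scope by design. The permutation framework
prices exploratory multiplicity per site, not across body sites.
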