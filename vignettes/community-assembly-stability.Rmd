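---
title: "Neutral assembly and stability of rearing-water bacterial communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral assembly and stability of rearing-water bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquastab)
```

## The scientific setting

`aquastab` reimplements, as a tested workflow, the statistical analysis of a
microalgae-inoculation experiment on shrimp-rearing water: four treatment
groups (C control, N *Nannochloropsis oculata*, T *Thalassiosira
weissflogii*, M their mixture) x 3 tank replicates x 8 sampling days x 2
bacterial lifestyles (particle-attached PA on a 3 µm filter, free-living FL
on a 0.22 µm filter), giving 192 16S amplicon samples summarized as a ZOTU
(zero-radius OTU) count table. Three questions drive the analysis:

1. **Assembly**: how much of each community is consistent with neutral
   (stochastic) assembly, and does microalgal addition change that?
2. **Stability**: which treatment yields the most stable community, measured
   by the average variation degree (AVD)?
3. **Structure**: which design factors and nutrient covariates explain
   compositional variation (PERMANOVA, ANOSIM, MRPP, Mantel, PCoA, RDA,
   db-RDA)?

Raw-read processing (denoising, taxonomy assignment) is upstream and out of
scope; the workflow consumes count tables. Because the study's processed
tables are not redistributable at desk scale, a first-class synthetic
generator emulates the design so every stage is testable from code alone.

## The neutral community model

A taxon with relative abundance $p$ in the source metacommunity has, under
Sloan's neutral model, a local relative abundance $x$ distributed

$$x \sim \mathrm{Beta}\big(Nm\,p,\; Nm\,(1-p)\big),$$

where $N$ is the community size (mean reads per sample here) and $m$ the
immigration rate; the product $Nm$ measures how tightly local communities
track the metacommunity. With detection limit $d$ reads, the classical
approximation for the probability that the taxon is detected in a sample is
the beta upper tail

$$F(p) = 1 - I_{d/N}\big(Nm\,p,\, Nm\,(1-p)\big),$$

implemented by `predict_frequency()` and verified in the tests against
numerical quadrature of the beta density.

### Fitting

`fit_ncm()` estimates $Nm$ by unweighted nonlinear least squares of the
observed occurrence frequencies $f_i$ (fraction of samples where ZOTU $i$
has at least $d$ reads) against the model curve evaluated at the mean
relative abundances $\hat p_i$, optimizing $\log Nm$ with five starting
points ($Nm \in \{1, 10, 10^2, 10^3, 10^4\}$) to avoid the flat plateaus
this objective can have. $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ uses SST
around the mean observed frequency (the standard convention; it may be
negative and is reported as-is). ZOTUs never detected contribute a
degenerate $(0, 0)$ point and are excluded.

**Detection model.** For count data the event "detected" is a property of
the *read count*, which adds a binomial layer on top of the beta: the exact
detection probability is the beta-binomial tail
$P(c \ge d) = 1 - B(Nm\,p,\, Nm(1-p)+N)/B(Nm\,p,\, Nm(1-p))$ for $d = 1$.
The classical threshold form $F(p)$ ignores this layer; on data whose
generative process is exactly beta + binomial it inflates $\hat{Nm}$ by
roughly 20% at the scales used here, because taxa whose latent abundance
sits just below $d/N$ are still detected occasionally. `fit_ncm()` therefore
defaults to the count-aware curve (`detection = "count"`), which recovers
generative $Nm$ within a few percent; `detection = "threshold"` provides
the classical form. The two coincide as $N \to \infty$.

### Prediction band and partition

The 95% band around the fitted curve is a Wilson score interval for a
binomial proportion with success probability $F(\hat p_i)$ and $n = k$
samples, with two refinements, both needed for the band to mean what it
claims:

* **Abundance-axis noise.** $\hat p_i$ is itself an estimate; for rare taxa
  its sampling noise, mapped through the slope of $F$, dominates the
  binomial width. The per-taxon effective sample size is shrunk to
  $F(1-F)\big/\big(F(1-F)/k + (\partial F/\partial p)^2\,\widehat{\mathrm{var}}(\hat p_i)\big)$
  (delta method). Without this, 15–20% of taxa in *pure neutral*
  simulations fall outside a nominal 95% band.
* **Binomial envelope.** The Wilson normal approximation collapses near
  $F \to 1$ (and 0): a taxon predicted present with probability
  $1 - 10^{-10}$ and observed in all $k$ samples is behaving exactly as
  predicted, yet sits above any interval whose upper bound is strictly
  below 1. The band is therefore the union of the Wilson interval and the
  exact binomial quantile envelope
  $[\,q_{\alpha/2}(k, F)/k,\; q_{1-\alpha/2}(k, F)/k\,]$.

ZOTUs above the band are partitioned `above` (occurring more often than
predicted), below it `below`, inside it `neutral`. Under pure neutrality at
$S = 1000$, $k = 50$ about 98% of taxa fall inside; with 30 injected `above`
and 30 `below` taxa, label recovery is 100% in the tested conditions.
`partition_abundance()` reports per-partition ZOTU counts and cumulative
mean relative abundance (the "neutral cumulative abundance" statistic);
`partition_by_family()` resolves the same summary by taxonomic family.

## The AVD stability index

For one sample group with $k$ samples, the variation degree of OTU $i$ in
sample $j$ is

$$a_{ij} = \frac{|x_{ij} - \bar x_i|}{\delta_i},$$

with $\bar x_i$ and $\delta_i$ the within-group mean and standard deviation
of the OTU's rarefied abundance, and

$$\mathrm{AVD} = \frac{\sum_{i}\sum_{j} a_{ij}}{k \times n}$$

over the $n$ OTUs of the group; lower AVD is read as higher stability.
Conventions the index's definition leaves open, and the package's choices:

* $\delta_i$ uses the sample SD (divisor $k - 1$); `ddof = 0` switches to
  the population SD. With $k = 2$ and `ddof = 1`, every non-degenerate OTU
  contributes exactly $\sqrt 2$ over its two samples, so AVD $= 1/\sqrt 2$
  — an exact regression test.
* Zero-variance OTUs carry no dispersion information; they are excluded
  from numerator *and* $n$ by default (`zero_variance = "exclude"`), or
  kept as zero contributions (`"zero"`).
* The absolute value is applied inside the sum (a signed degree averaged
  over samples would cancel toward 0 by construction).
* Inputs are rarefied counts; the pipeline rarefies to the minimum sample
  total by default. The rarefaction depth for the source study is not
  recorded anywhere we can recover, so it is a configuration knob.
* Significance testing needs replicate-level values; `avd_by_stratum()`
  computes one AVD per tank replicate across its time series by default,
  with per-timepoint and bootstrap alternatives (`replicate_unit`), since
  the original figure's error structure is not documented.

**What AVD measures — and a caution.** AVD is invariant to rescaling any
OTU's abundances (the scale cancels in $|x - \bar x|/\delta$): it is a pure
*shape* statistic, the mean standardized absolute deviation, and does *not*
decrease merely because abundances fluctuate less. For near-normal
fluctuations it approaches $\sqrt{2/\pi} \approx 0.80$; zero-inflated or
strongly skewed OTU distributions push it *down*. Consequently, in neutral
simulations a *larger* $Nm$ (tighter coupling, more nearly normal counts)
yields a *larger* AVD, not a smaller one — the intuition "less variance, so
lower AVD" is wrong, and one acceptance-level check encoding that intuition
fails by design (10/10 seeds in the opposite direction at both tested
scales). Comparisons of AVD across groups with similar distributional
shapes remain meaningful; interpreting AVD differences as variance
differences does not.

## The synthetic study generator

`simulate_study()` produces data whose statistical structure matches what
the analysis assumes, not a mechanistic pond model:

* One lognormal metacommunity (`abundance_sigma = 1.5`, a typical amplicon
  rank-abundance shape; $S = 1000$ taxa) shared by all samples.
* Each design cell is an independent beta draw with the group's $Nm$,
  sequenced as per-taxon Binomial$(N, x_{ij})$ with $N = 20\,000$ reads.
  Totals vary around $N$ and are not renormalized, matching the per-taxon
  detection model the fit assumes. Beta parameters are floored at $10^{-8}$;
  taxa with both parameters below $10^{-6}$ are treated as absent.
* Default per-group $Nm$: C 1500, N 1000, M 800, T 600 — the control
  community assembles most neutrally, the *T. weissflogii* group least,
  qualitatively matching the study's narrative. Per-lifestyle multipliers
  exist but default to 1 (the source text gives no basis for a lifestyle
  difference in assembly parameters).
* Nutrient covariates are group-specific linear trends plus Gaussian noise,
  clamped at 0. Intercepts sit near day-0 water; slopes are back-solved so
  each group's mean over the 8 sampling days lands near the observed group
  means (nitrate and phosphate rising faster under microalgal addition,
  ammonium and nitrite flat). Both lifestyle fractions of a tank share its
  chemistry. This deliberately simple generator exists to exercise the
  Mantel/RDA/ANOVA plumbing, not to model pond chemistry.
* `inject_non_neutral()` creates known neutrality violations: `above` taxa
  are rare taxa forced detected in every sample (one read donated by the
  sample's most abundant taxon); `below` taxa are abundant taxa zeroed in
  80% of samples with their reads reallocated proportionally, conserving
  sample totals exactly.
* All randomness flows from one root seed; identical configs are
  bit-identical. Rarefaction draws one hypergeometric subsample per sample,
  seeded by (seed, sample index).

Passing tests on these data show that the estimators recover known
generative structure; they do not show that real rearing-water communities
satisfy the model (real data have temporal autocorrelation, compositional
coupling between taxa, and chemistry feedbacks the generator omits).

## Distance-based statistics

All implemented in-package and cross-checked in the tests against
independent references (vegan, ape, stats) on shared inputs:

* **Bray–Curtis** on relative abundances by default (robust to unequal
  depth); raw/rarefied counts optional.
* **PCoA**: eigen-decomposition of the Gower-centered matrix; negative
  eigenvalues reported as-is by default, Lingoes correction behind a flag.
* **PERMANOVA**: sequential (Type I) sums of squares in the user's term
  order — a single $R^2$ per term with interactions implies sequential
  attribution — via projector traces on the Gower matrix; pseudo-F against
  the full-model residual; free permutation of sample labels (no
  restriction by time, which also matches how the original tables read);
  exhaustive enumeration available for small $n$.
* **ANOSIM** with average ranks for ties; **MRPP** with group-size weights
  $n_g/n$ and chance-corrected $A = 1 - \delta/E[\delta_{perm}]$;
  **Mantel** Spearman by default (ranks assigned to the distance matrix
  once — a joint row/column permutation preserves the value multiset).
* Every permutation p-value uses the $(1 + b)/(1 + n_{perm})$ estimator, so
  p is never 0 and is reproducible for a fixed seed.
* **RDA** on Hellinger-transformed counts; inertia as variance (SS/(n−1));
  overall pseudo-F by row permutation. **db-RDA** feeds PCoA axes
  retaining ≥ 99.9% of positive inertia into RDA, which makes the
  Euclidean-input equivalence with plain RDA exact to numerical precision
  while excluding numerically-zero axes.
* **One-way ANOVA + Tukey HSD** (delegated to `stats::aov`/`TukeyHSD`) with
  an insert-and-absorb compact letter display; ties in letter assignment
  broken by first appearance order.
* **UPGMA** clustering with deterministic lexicographic tie-breaking and
  Newick serialization (leaf branch length = merge height / 2).

## Numerical and degenerate-input conventions

* $Nm$ is optimized on the log scale in $[10^{-3}, 10^9]$; an all-constant
  frequency spectrum, fewer than 10 detected ZOTUs, or fewer than 2 samples
  are errors, as are zero-total samples in normalization and distances.
* `predict_frequency` pins $F(0) = 0$ and $F(1) = 1$ exactly.
* Aliased PERMANOVA terms (no added rank) and collinear RDA constraints are
  errors naming the offending term/columns.
* Distance matrices must be symmetric to $10^{-12}$ with zero diagonal;
  Bray–Curtis output is symmetrized against floating-point drift.
* `nutrient_change` subtracts each tank's day-0 baseline (group x
  replicate x lifestyle); the subtraction direction is a flag because the
  source tables print a sign convention that cannot be reconciled with
  rising concentrations under "final − initial". Missing covariate cells
  propagate as missing, never imputed.

## Problem sizes

The test suite and the analysis scripts run everything at the design scale
(192 samples) with $S = 1000$ taxa and $N = 20\,000$ reads per sample;
parameter-recovery and calibration checks use $S = 1000$, $k = 50$,
$N = 10\,000$ over 10 seeds and 500–1000 null datasets with 199–999
permutations. These sizes were chosen so the whole workflow re-runs from
scratch in minutes on one core while keeping every estimator in the regime
where its asymptotics are meaningful.

## Known limitations

* The generator has no temporal autocorrelation, so "time" effects in the
  synthetic PERMANOVA are pure noise; the term exercises the machinery, not
  a biological claim.
* AVD comparisons across groups are shape-sensitive (see above); the
  package reports the index as defined and leaves interpretation to the
  analyst.
* db-RDA drops negative-eigenvalue axes; for strongly non-Euclidean
  dissimilarities the constrained proportion refers to the retained
  positive-inertia subspace.
* The NCM treats taxa independently; compositional coupling (reads summing
  to the depth) is ignored by both the simulator and the fit, consistent
  with the model's standard use.
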