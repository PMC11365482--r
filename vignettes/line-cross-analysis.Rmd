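---
title: "Information-theoretic line cross analysis with linecross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic line cross analysis with linecross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linecross)
```

## The method

Line cross analysis (LCA) asks how the phenotypic divergence between two
lines is built out of modes of gene action.  Two founder strains (P1, P2)
and cohorts derived from them by crossing (F1, F2, backcrosses) each carry
a known expected dose of every *composite genetic effect* — the summed
contribution of one mode of gene action across all loci affecting the
trait.  Writing those doses as the c-matrix $C$ (cohorts $\times$
effects), the cohort phenotype means follow the linear model

$$\bar z_j = \mu + \sum_e c_{je}\,\beta_e + \varepsilon_j,
  \qquad \varepsilon_j \sim N(0, \mathrm{SE}_j^2),$$

where $\mu$ is the grand mean, $\beta_e$ the composite effects, and
$\mathrm{SE}_j$ the (known) standard error of cohort $j$'s mean.  With
five cohorts the identifiable effect set has ten members: autosomal
additive (Aa) and dominance (Ad), cytotype additive (Ca, the
maternal-lineage organellar contribution), maternal additive and
dominance (Mea, Med — the dam's own Aa and Ad states), and the five
two-way epistatic products AaAa, AaAd, AdAd, AaCa, AdCa.

Rather than fitting one pre-chosen model, the analysis fits *every*
estimable subset of effects by weighted least squares (weights
$1/\mathrm{SE}_j^2$), scores each model by small-sample-corrected AIC,
and model-averages over a 95% confidence set of models, so that the
reported architecture carries model-selection uncertainty with it.

## Coefficient derivation

`cmatrix()` derives all coefficients by recursion over the pedigree:

* $\theta$, the expected P1 genome proportion, is 1 for the P1 founder,
  0 for P2, and the parental average for any cross; $Aa = 2\theta - 1$.
* $Ad$ is expected heterozygosity under independently sampled parental
  gametes: $Ad = \theta_s(1-\theta_d) + \theta_d(1-\theta_s)$, zero for
  founders.  The independence assumption is exact for crosses among P1,
  P2, their F1 and combinations thereof (F2, backcrosses) — the
  supported pedigree class.  Advanced intercross generations beyond this
  class would need gamete-distribution bookkeeping the package does not
  attempt.
* $Ca$ follows the strict dam lineage to a founder ($+1$ for P1, $-1$
  for P2); a founder's cytotype is itself and selfing preserves it.
* $Mea$ and $Med$ are the dam's $Aa$ and $Ad$.
* Epistatic coefficients are elementwise products of their two
  constituent columns; anything beyond two-way products is rejected,
  because a five-cohort design cannot separate higher-order terms.

Coefficients are kept on the $\pm 1$ parental scale (founders at $Aa =
\pm 1$).  Parts of the LCA literature use a $\pm\tfrac12$ scale; the
$\pm 1$ convention is used consistently here and only rescales the
$\beta$ units, not the inference.

```{r}
cmatrix(solanum_pedigree())
```

## Cohort summaries from nested measurements

Leaves measured on the same plant are pseudo-replicates.  The cohort
mean is therefore the unweighted mean of plant means, and the cohort SE
is

$$SE = \sqrt{\sum_{i=1}^{n} \sigma_i^2 / s_i},$$

with $\sigma_i$ the replicate SD (denominator $n-1$) and $s_i$ the
replicate count of plant $i$.  Two deliberate conventions:

* The formula is implemented exactly in this form, without a $1/n$
  factor — it is the SE of the *sum* of plant means.  The variant that
  divides by $n$ is available as `se_of_mean_of_means()` but is never
  the default, because the headline analyses this package targets were
  produced with the form above.
* A plant observed once has no sample SD; it contributes $\sigma_i = 0$
  and a warning.  Individually weighed seeds are the intended case:
  each seed is a one-observation "plant", and with all $\sigma_i = 0$
  the SE must instead come from simulating or supplying summary input.

## Model space, AICc, and averaging

A model is any subset of effects (the grand mean is always present).
`enumerate_models()` keeps the subsets whose design matrix — intercept
plus selected c-matrix columns — has full column rank, judged by
singular values with a relative cutoff of $10^{-8}$ times the largest
one; the dependencies of the five-cohort matrix (e.g. $AdAd =
\tfrac12 Ad$, or $AaCa = 1 - Aa + Ca$ row-wise) are exact rationals,
so the cutoff is not delicate.  For the standard design with subsets of
up to four effects this yields 243 estimable models (the software that
introduced this analysis reports a nearby 241 under an unprinted
filter; the count here is pinned as a regression fixture).

Each model is fit by generalized least squares with the cohort SEs
treated as known variances.  That convention makes the Gaussian
log-likelihood

$$\ell = -\tfrac12\Big[\sum_j \frac{(\bar z_j - \hat z_j)^2}{\mathrm{SE}_j^2}
 + \sum_j \ln\!\big(2\pi \mathrm{SE}_j^2\big)\Big]$$

well-defined even for saturated models, and

$$\mathrm{AICc} = -2\ell + 2K + \frac{2K(K+1)}{n - K - 1}$$

with $K$ = intercept + effects and $n$ = number of cohorts.  Models
with $n - K - 1 \le 0$ get an infinite-AICc sentinel: they stay listed
in the model-space report but receive zero weight.  Enumeration and
weighting are deliberately decoupled — the model space is reported in
full even where the small-sample correction refuses to rank.

Akaike weights $w_i \propto e^{-\Delta_i/2}$ are computed over the
finite-AICc models; the confidence set is the smallest prefix of the
weight-sorted models reaching cumulative weight 0.95 (AICc ties keep
model order, so the set is deterministic).  Averaging uses
zero-substitution over the confidence set with renormalized weights: an
effect absent from a model contributes 0 there, so weak effects shrink
toward zero.  The unconditional standard error
$\sum_i w_i \sqrt{\mathrm{se}_i^2 + (\beta_i - \bar\beta)^2}$ folds
model-selection spread into the parameter uncertainty.  Variable
importance is the summed weight of confidence-set models containing the
effect.  Whether the original software renormalizes within the
confidence set or averages with full-set weights is not documented;
renormalization matches the "within the confidence set" definition of
variable importance and is the default, with `scope = "all"` as the
alternative convention.

An effect is *included* when its variable importance strictly exceeds
0.5 and its estimate differs from zero by strictly more than one
unconditional SE.  The one-SE reading takes "a standard error that
excludes zero" literally; `se_multiplier` exposes stricter multiples
(e.g. 1.96).  Included effects are pooled by mode of gene action —
additive (Aa, Ca), dominance (Ad), epistatic (the five products),
maternal (Mea, Med) — with contributions $|\hat\beta_e|$ scaled to sum
to one.  Maternal effects appear only in the maternal column.  When
nothing passes, the trait's row is all-`NA`: no architecture can be
inferred, which is itself a finding about model-selection uncertainty.

```{r}
cm <- cmatrix(solanum_pedigree())
s <- data.frame(cohort = rownames(cm), trait = "length",
                mean = c(14.1, 5.9, 10.1, 12.0, 8.0), se = 0.4)
fit <- lca(s, cm)
fit$architecture
head(model_report(fit$traits$length), 3)
```

## The synthetic-data generator

`simulate_cohorts()` draws plant-nested Gaussian data around the exact
expectation $\mu + C\beta$: plant effects with SD `sigma_plant`, then
replicate observations with SD `sigma_obs`.  Its defaults reproduce the
study layout the package was validated against — five cohorts, two
plants each, 23/14/13/14/21 leaves over P1, P2, F2, BC1, rBC2 — with a
grand mean of 10, a single additive effect $\beta_{Aa} = 4$,
`sigma_plant = 0.5` and `sigma_obs = 1`.  The noise SDs are chosen once
as a realistic regime for leaf-morphometric data: the within-plant
replicate scatter dominates, and the implied cohort SE
($\approx 0.4$–$0.5$ trait units) sits an order of magnitude below the
parental divergence, comparable to the measured traits.  Gaussian noise
at both levels matches the WLS working model, which keeps recovery
experiments interpretable as checks of the inference machinery rather
than of distributional robustness.

What the generator deliberately does not emulate: segregation-variance
inflation in F2/backcross cohorts (real hybrid cohorts are more
variable than parents; here all cohorts share one noise model),
genotype-by-environment interaction, linkage, and non-Gaussian
measurement error.  A passing recovery test therefore demonstrates that
the estimator chain is correct under its own assumptions — not that
those assumptions hold for any particular greenhouse.  Per-cohort RNG
streams are derived deterministically from the single seed, so datasets
are reproducible cohort by cohort.

`recovery_experiment()` wraps the full pipeline over seeded replicates
and reports per-effect inclusion fractions (power for true effects,
spurious-inclusion rate under a null architecture), bias, and the rate
of exact recovery of the true effect set.  At the default study-scale
settings, 200 replicates run in well under a minute; the validation
suite uses that size, with 500-plant layouts only for the convergence
check of the generator itself.

## Numerical and design notes

* **Rank tolerance**: $10^{-8}$ relative singular-value cutoff;
  exact-rational dependencies sit at 0, well clear of it.
* **Ties**: deterministic everywhere — models ordered by size then
  lexicographic label order; AICc ties resolved by model order when
  sorting for the confidence set.
* **Zero SEs** are rejected with instructions rather than silently
  regularized: a zero-SE cohort would get infinite weight.
* **Degenerate inputs**: traits missing from some cohorts are
  summarized for the cohorts present (with a warning) but cannot be
  fit; an all-infinite AICc vector is an error, not an empty set.
* **Compound traits** (ratios of elemental traits) pass through the
  pipeline like any other trait; no delta-method correction of their
  SEs is attempted.

## Limitations

The supported pedigree class is the one the heterozygosity recursion is
exact for (founders, F1, and their crosses).  Maternal-by-nuclear and
higher-order epistatic terms are not identifiable from five cohorts and
are rejected rather than estimated.  Cohort SEs are treated as known,
so the method inherits the usual small-$n$ optimism of plug-in
variances; with two plants per cohort the between-plant variance is
estimated from one degree of freedom and enters the SE only through the
within-plant term.  These are properties of the published design the
package reproduces, not choices it can relax.
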