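---
title: "Bayesian bivariate variable selection for longitudinal pedigree traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian bivariate variable selection for longitudinal pedigree traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsur)
```

# The model

`pedsur` fits a joint model for two quantitative traits (think diastolic
and systolic blood pressure) measured at repeated visits on members of
extended pedigrees, with simultaneous selection over a candidate set of G
SNVs. For trait $k \in \{1,2\}$ of subject $j$ in family $i$ at visit $t$:

$$
y_{ijtk} = \beta_{0k} + X_{ij}'\beta_{xk} + Z_{ijt}'\beta_{zk}
  + \sum_{g=1}^{G} \gamma_{gk}\,\beta_{gk}\,\mathrm{SNV}_{ijg}
  + p_{ik} + s_{ijk} + e_{ijtk}
$$

with three bivariate Gaussian layers,
$p_i \sim N_2(0, \Sigma_p)$ (family), $s_{ij} \sim N_2(0, \Sigma_s)$
(subject), and $e_{ijt} \sim N_2(0, \Sigma_e)$ (visit-level residual). The
family layer captures shared environment and (coarsely) shared genetics;
the subject layer the correlation among a subject's repeated measures; and
the residual layer correlates the two traits at the same visit, exactly as
errors are coupled across equations in seemingly unrelated regressions.
Visit counts $m_{ij}$ may differ between subjects, but both traits must be
observed at the same visits (intake enforces this).

Assumptions worth stating plainly:

* relatedness enters only through the family random effect — there is no
  kinship-matrix polygenic term, so within-family differences in
  relatedness (siblings vs cousins) are not distinguished;
* SNV effects are additive in dosage, constant over time, and sparse;
* time itself has no functional trend — visits are exchangeable given the
  time-varying covariates (age carries the secular trend).

## Selection prior and multiplicity

Each SNV-by-trait pair carries an inclusion indicator
$\gamma_{gk} \sim \mathrm{Bernoulli}(q_k)$ with $q_k \sim \mathrm{Beta}(a, b)$,
and a slab $\beta_{gk} \sim N(0, \tau^2)$ when included. With the default
$a = 1$, $b = G$ the marginal prior odds that any given pair is included is
$1/G$: the prior concentration scales with the candidate set, so enlarging
G with noise SNVs does not enlarge the expected number selected. This is
the Bayesian counterpart of a multiplicity correction, and the all-noise
scenarios in the test suite confirm near-zero false positives at both
G = 30 and G = 60 at the PIP $\ge 0.5$ threshold.

We use one $q_k$ per trait. A single shared $q$ is defensible too (the
prior is written with one $q$); per-trait $q$ preserves the $1/G$ marginal
prior odds within each trait and keeps the traits' sparsity levels
decoupled, which matters when one trait has more active variants than the
other. `chainConfig(sharedQ = TRUE)` gives the pooled reading.

## Priors and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `a`, `b` | 1, G | Beta layer on inclusion probability |
| `tau2` | 100 | slab variance, on the standardized-trait scale |
| `v0` | 1e4 | prior variance of intercept/covariate coefficients |
| `nu0`, `S0` | 3, 0.01·I | inverse-Wishart df and scale for all three covariance layers |

Traits are standardized internally (mean 0, SD 1) before fitting, and all
reported coefficients and covariance draws are transformed back to the raw
trait scale. This makes a single default slab variance defensible: on the
standardized scale $\tau^2 = 100$ is diffuse for any plausible effect.
Dosage columns are centered but not scaled, so SNV coefficients stay on
the per-minor-allele scale of the trait's units. A consequence of
centering is that reported intercepts refer to the centered-dosage design.

With `nu0 = 3` the inverse-Wishart is as diffuse as a finite-mean prior
allows, and the implied prior on each correlation is flat on $(-1, 1)$.
With only I = 20 families, $\Sigma_p$'s correlation is weakly identified
and its posterior can wander far from the truth; this is a property of the
data configuration, not the sampler (at I = 100 with a strong family
signal the posterior concentrates tightly on the generating values).

# The Gibbs sampler

One sweep updates, in a fixed scan order: all active regression
coefficients (both traits jointly, whitened by $\Sigma_e^{-1}$); each
$(g,k)$ indicator; $q_k$; family effects; subject effects; the three
covariance layers. The fixed order is for reproducibility — Gibbs
correctness does not depend on it.

The indicator update is collapsed: $\beta_{gk}$ is integrated out
analytically against the trait-$k$ likelihood conditional on the other
trait's current residuals (through the bivariate residual regression
$e_k \mid e_{k'} \sim N(c\,e_{k'},\, v)$ with
$c = \Sigma_{e,kk'}/\Sigma_{e,k'k'}$). This gives the conditional Bayes
factor in closed form, avoids the mixing pathologies of joint
$(\gamma, \beta)$ proposals, and needs no pseudo-prior tuning. When
$\gamma_{gk} = 0$ the stored coefficient is 0 — with the collapsed update
the stored value never enters the kernel. A zero-variance (after
centering) dosage column yields Bayes factor exactly 1, so its inclusion
probability is just $q_k$; the same holds in the $\tau^2 \to 0$ limit.

Conjugacy details: $q_k \sim \mathrm{Beta}(a + n_k,\; b + G - n_k)$ given
$n_k$ inclusions; random effects have bivariate normal full conditionals
with precision $\Sigma^{-1}_{\text{layer}} + m\,\Sigma_e^{-1}$; the
covariance layers are inverse-Wishart with degrees of freedom incremented
by exactly the number of contributing vectors. Each of these closed forms
is checked against independent derivations in the tests (the random-effect
conditional against Schur-complement conditioning of the explicit joint
Gaussian; the indicator update against 1-D quadrature).

**Univariate mode** (the first comparator) fits the same model with all
cross-trait covariances forced to zero. It is implemented as two
independent single-trait chains with scalar variances (inverse-gamma
$\sigma^2 \sim IG(\nu_0/2, S_{0,kk}/2)$, the 1-D marginal of the
inverse-Wishart layer), each with its own derived seed. This makes trait-1
results exactly invariant to anything done to trait 2 — a property the
test suite asserts bitwise.

## Validation strategy

Two independent oracles guard the sampler:

1. **Joint-distribution (Geweke) test** (`gewekeJointTest()`): compare
   independent prior draws against a chain that alternates data
   re-simulation with one Gibbs sweep. Any error in a full conditional
   shows up as a diverging z-score on some monitored functional
   (coefficients, $q$, all covariance entries, random-effect components).
   Run at 20,000 draws on a micro design with proper, mildly informative
   priors ($v_0 = \tau^2 = 1$, $a = b = 2$, $\nu_0 = 6$, $S_0 = I$ — test
   priors, not analysis defaults, chosen so every prior moment used by the
   test is finite).
2. **Exact enumeration** (`exactInclusionProbabilities()`): with the
   covariance layers held fixed, every Gaussian latent integrates in
   closed form, so exact PIPs follow from enumerating all $2^G \times 2^G$
   joint models with Beta-Bernoulli weights (the full stacked
   $2n$-dimensional marginal likelihood, so the cross-trait coupling path
   is exercised too). At G = 4 the Gibbs PIPs agree to well within 0.02.

## Numerical choices

* Cholesky factorizations symmetrize first and retry once with a
  $10^{-10}$-scaled jitter before erroring.
* Initialization: per-trait least squares on the fixed effects, indicators
  all zero, $q_k = a/(a+b)$, random effects zero, covariance layers
  diagonal with the residual variance split by a within-subject/total
  decomposition. Initialization only affects burn-in.
* Chains are deterministic given `chainConfig(seed=)`: one seeded R RNG
  stream per chain (one per trait in univariate mode).
* Monte Carlo standard errors use non-overlapping batch means, 20 batches.
  Indicator chains for borderline SNVs mix in bursts; their PIP estimates
  carry the largest MC error and stability should be checked with
  `pipStability()`.

# The synthetic-data generator

The generator (`simConfig()`, `simulatePedigreeStructure()`,
`dropGenes()`, `simulatePhenotypes()`) emulates a GAW-style family
blood-pressure study: ~20 multigenerational pedigrees built from founder
couples (2–5 children per couple, a fraction marrying in across 3
generations, giving family sizes averaging ~40–50 in the 21–75 range),
three visits per subject, genotypes realized by gene dropping (founder
alleles Bernoulli(MAF), children inheriting one uniformly chosen allele
per parent), and phenotypes drawn from the model above on the
blood-pressure scale (intercepts 75/120; sex, smoking and age covariates;
cross-trait correlation 0.7 in each layer — the observed DBP–SBP
correlation in such studies is around $r^2 \approx 0.55$). An optional
medication layer marks visits with latent SBP above a threshold as
hypertensive, medicates a fraction of those subjects, and shifts their
observed values additively — so the medication adjustment can be exercised
end to end.

`gawLikeScenario()` is the benchmark frame: 15 causal SNVs with their
published founder MAFs and additive effect pairs (one of them with a null
printed effect, hence in neither causal truth set), plus a titrated number
of noise SNVs (1, 15, 30, 60 or 90; 90 noise gives the 105-column frame).
Candidate SNVs are conditioned on segregating in the founders, as a
genotyped panel's variants are.

Simulated LD is off by default (noise SNVs independent). For testing the
LD discounting of false positives, LD pairs are built by copying a source
SNV's founder alleles with a small per-allele flip probability
$\varepsilon$ and transmitting the two loci in perfect linkage; the
resulting dosage $r^2$ is near $(1-2\varepsilon)^2$ and is calibrated
empirically in the tests.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: no recombination or realistic LD maps, no
ascertainment (families are not sampled for being hypertensive), no
genotyping error or missingness mechanisms, no secular or cohort effects
beyond linear age, and Gaussian layers throughout (real BP is
right-skewed and medication use is not a simple threshold process).

## Problem sizes in the tests

The validation suite runs at desk scale by choice: the recovery scenario
uses 20 families of ~10 subjects (about 560–680 observations), G = 10,
and 3,000–5,500 sweeps; multiplicity scenarios use the same families with
G = 30 and 60; the Geweke and enumeration checks use micro designs (12–24
observations) where their guarantees are exact. Because a ~200-subject
study carries about a quarter of the information of a full-size one, the
recovery scenario scales the covariance layers down (SDs roughly halved)
so that per-SNV information matches the regime in which strong rare
variants (effects −5 to −10, MAF 0.03–0.05) are detectable — that is what
makes "every causal PIP ≥ 0.5" a fair recovery bar rather than a coin
flip on the realized number of carriers.

# Preprocessing choices

**Medication adjustment.** Among hypertensive observations, the trait-wise
mean difference $\delta_k$ between medicated and unmedicated observations
is subtracted from every medicated hypertensive observation, imputing its
unmedicated value. Strata pool all visits and subjects (observation-level
means); each trait gets its own $\delta$; the subtraction applies whatever
$\delta$'s sign. If no observation is medicated the table passes through
unchanged; a medicated stratum without an unmedicated counterpart is an
error, since $\delta$ is then inestimable.

**LD utilities.** $r^2$ is the squared Pearson correlation of dosage
vectors (composite LD) — appropriate for unphased family data, with no
haplotype phasing or EM. A selected noise SNV counts as LD-explained when
its maximum $r^2$ with any selected causal SNV reaches 0.8.

**Intake.** Missing covariates are a hard error (no imputation — silent
imputation would change the model). Individuals with genotypes but no
phenotypes stay in the pedigree but contribute no likelihood rows;
phenotyped individuals without complete genotypes are an error by default
(droppable by flag, logged). Monomorphic SNVs are dropped with a warning
and G updated, since their Bayes factor is identically 1 and they would
only dilute the $1/G$ prior odds.

# The comparators

`runUnivariate()` is the univariate Bayes baseline described above.
`mgaScan()` stands in for the classical measured-genotype approach: single
trait, single SNV, first visit only, a family random intercept (not a
kinship matrix — consistent with the main model's own design), maximum
likelihood (not REML, since the compared models differ in fixed effects),
and a 1-df likelihood-ratio test, Bonferroni-corrected over the candidate
count. Its role is behavioral — exhibiting false-positive inflation under
LD noise where the Beta-Bernoulli model stays clean — not replication of
any particular published implementation.

# Known limitations

* Exactly two traits; the covariance layers are hard-coded 2x2.
* No kinship-matrix polygenic covariance; relatedness is family-block.
* The collapsed indicator update integrates one coefficient at a time;
  with many highly collinear candidates (tight LD blocks) the chain can
  alternate between tagging SNVs, splitting the PIP across the block —
  summarizing blocks jointly is then more faithful than per-SNV PIPs.
* Conditional-on-inclusion coefficient summaries for low-PIP SNVs rest on
  few draws; `nInclusionDraws` is reported so such estimates can be
  discounted.
* The enumeration oracle is exact but exponential in G (practical to
  G ≈ 6); it is a validation tool, not an inference path.
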