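---
title: "Small-area smoking prevalence and attributable mortality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area smoking prevalence and attributable mortality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

National health interview surveys measure smoking reliably at the national
and regional level, but sample only a fraction of municipalities — typically
a quarter of them, with anywhere from a handful to a few hundred respondents
each. Direct survey estimates of municipal smoking prevalence are therefore
either unavailable (off-sample municipalities) or wildly unstable (they can
span 0 to 100% purely through sampling noise). Yet municipal smoking
prevalence is exactly what is needed to localize the mortality burden of
tobacco. `smokesae` implements the full chain from survey microdata to
municipal smoking-attributable mortality, and ships a synthetic-data
generator with known ground truth so every stage can be validated end to
end.

# Design-based direct estimation

For a binary smoking indicator $y_{ik}$ with inclusion probabilities
$\pi_{ik}$ and design weights $w_{ik} = 1/\pi_{ik}$, the package estimates
area prevalence with the Hájek (weight-normalized) ratio

$$\hat p_i = \frac{\sum_{k \in s_i} w_{ik} y_{ik}}{\sum_{k \in s_i} w_{ik}},$$

not the unnormalized inverse-probability total: the total estimates a
population *count*, and dividing by the estimated population size is what
makes it a prevalence. This normalized form is also invariant to rescaling
all weights, which the tests verify. Post-stratified weights are used by
default (matching survey practice); a flag selects raw design weights.

The design variance is estimated by cluster-level Taylor linearization of
the ratio (clusters = households) under a with-replacement first-stage
approximation, standard when sampling fractions are small. On toy designs
the linearized variance is checked against brute-force enumeration of all
cluster resamples; the agreement is exact for balanced cluster weights and
degrades only in regimes (two clusters with strongly unequal weight totals)
where any linearization of a ratio fails.

Areas whose direct estimate is degenerate ($\hat p_i \in \{0, 1\}$ or zero
variance) are flagged and *excluded from the smoothing likelihood* rather
than continuity-corrected: their logit-scale variance is undefined, and
exclusion lets the model treat them exactly like off-sample areas. The
trade-off of this choice is discussed under *Limitations*.

# The smoothing model

The logit of each usable direct estimate is modelled as Gaussian with known
design variance $\hat V_i$ (delta method):

$$\mathrm{logit}(\hat p_i) \sim N(\theta_i, \hat V_i), \qquad
\theta_i = x_i^\top \beta + b_i,$$

with area covariates $x_i$ (population shares of education, age, gender —
standardized across areas) and a BYM2 random effect

$$b = \sigma\left(\sqrt{\phi}\, u^* + \sqrt{1-\phi}\, v\right),$$

where $u^*$ is the *scaled* intrinsic CAR (ICAR) component on the
municipality adjacency graph, $v$ is iid standard normal, $\sigma \ge 0$ is
the total random-effect scale and $\phi \in [0,1]$ the spatial mixing
fraction. The ICAR precision of each connected component is multiplied by
the geometric mean of its constrained pseudo-inverse diagonal, so that
$u^*$ has unit generalized marginal variance and $\sigma$ has the same
interpretation on any graph. Sum-to-zero constraints are imposed per
connected component; singleton components carry no structured effect and
rely entirely on $v$.

Priors: $\sigma$ carries the penalized-complexity prior for a Gaussian
scale, an exponential with rate $-\log(\alpha)/u$, parameterized as
$P(\sigma > u) = \alpha$ with defaults $u = 1$, $\alpha = 0.01$; $\beta$ is
zero-mean Gaussian with small precision (0.001); $\phi$ is uniform on
$[0,1]$ — the mixing prior is not pinned down by the applications this
package follows, so it is deliberately the flattest choice and is
configurable.

## Inference

Inference is by MCMC, not by a Laplace approximation: the package owns its
sampler so that every conditional is transparent and testable.

* $(\beta, u, v)$ are updated jointly from their Gaussian full conditional
  (a sparse-precision normal; the sum-to-zero and singleton constraints are
  imposed exactly by conditioning-by-kriging on the sampled vector).
* $(\log \sigma, \mathrm{logit}\,\phi)$ are updated by random-walk
  Metropolis in the *non-centered* parameterization, with Robbins-Monro
  adaptation of the step sizes during burn-in (target acceptance 0.35).
* A second, *centered* update of $\sigma$ (given $b$, integrating over the
  eigenbasis of the scaled ICAR precision) is interwoven each scan, with
  $u, v$ rescaled to keep $b$ fixed. This ancillarity–sufficiency
  interweaving keeps mixing fast whether the data are weak or strong.

Defaults are 4 chains of 5,000 iterations with 2,000 burn-in; convergence
is flagged by split-chain $\hat R > 1.05$ on $\beta, \sigma, \phi$ (a
warning, never a silent success). Off-sample and degenerate areas receive
posterior draws of $\theta_i$ through the conditional of $b$ given its
neighbors — this is where strength is borrowed.

Correctness anchors (all in the test suite):

* with $\sigma$ fixed at 0 the sampler reproduces the closed-form conjugate
  Gaussian posterior of $\beta$ to within 1%;
* the ICAR scaling factor matches a dense pseudo-inverse oracle to 1e-10;
* importance-sampling CPO matches brute-force leave-one-out refits to
  within 10% (in practice well under 1%);
* on the recovery benchmark (100-area grid, 60 in-sample areas of $n=50$,
  $\beta = (-1.5, 0.8)$, $\sigma = 0.5$, $\phi = 0.5$) the posterior means
  of $\beta$ are recovered and 95% credible intervals cover true area
  prevalences at close to nominal rate (measured ~92-93% across 50
  replicates).

Model assessment uses DIC ($\bar D + p_D$ from the Gaussian deviance on the
logit scale) and per-area conditional predictive ordinates, estimated by
the harmonic-mean identity from full-posterior draws with an
effective-sample-size stability flag.

# From binary fits to a five-category composition

Separate binary models are fitted for the nested ladder heavy ⊂
heavy+moderate ⊂ current ⊂ ever; posterior draws are paired by index
across fits (the pipeline gives every ladder fit the same seed) and
differenced downward: moderate = (heavy+moderate) − heavy, and so on;
never = 1 − ever. Because the fits are independent models, a difference
can be negative; negative differences are clamped to zero and each draw's
five-category vector is rescaled to sum to one. The tests verify that
every rescaled draw is a non-negative simplex to 1e-12, that rescaling is
the identity when no clamp fired, and that summaries match analytic Beta
quantiles on constructed draws.

Whether two or four binary fits should feed the ladder is genuinely open;
four is the default because it lets the heavy/moderate/light mix vary by
area, and the ladder is configurable. The price is that the rare heavy
category (≈2% nationally) is estimated from areas where a handful of heavy
smokers decide the direct estimate — see *Limitations*.

# Attributable fractions and deaths

With category prevalences $P_j$ and relative risks $RR_j$ (never smokers
the reference, $RR = 1$), the package uses the multi-category Levin
formula

$$\mathrm{PAF} = \frac{\sum_j P_j (RR_j - 1)}{1 + \sum_j P_j (RR_j - 1)},$$

whose denominator equals $\sum_j P_j RR_j$ summed over *all* categories
including never smokers — the only reading under which PAF stays in
$[0, 1)$ for $RR \ge 1$. Attributable deaths are
$\mathrm{SAM}_i = D_i \times \mathrm{PAF}_i$.

Relative risks come from a packaged table of four meta-analyses (point
estimate + 95% CI per category). Each is given a gamma distribution by
moment matching: the CI is read as symmetric normal,
$sd = (high - low)/(2 \times 1.96)$, then shape $= (point/sd)^2$ and rate
$=$ shape$/point$, so the gamma mean reproduces the point estimate
exactly. Monte-Carlo propagation pairs 1,000 posterior composition draws
with 1,000 independent gamma draws (both streams split from one seed);
1,000 draws is enough that doubling them moves area SAM means by well
under 2%.

Two scenarios, as in the application the package follows:

* **Scenario 1 (standardized):** both the stratum compositions and the
  death counts of each area are directly standardized to a standard
  population's six age-gender stratum shares before PAF is applied. The
  mechanics of the standardization are not uniquely determined by the
  source application; direct standardization of both inputs is this
  package's choice.
* **Scenario 2 (six strata):** PAF and SAM are computed within each
  age-gender stratum with crude stratum deaths and summed per area.
  Additivity over strata holds draw by draw, by construction and by test.
  The stratum-to-study mapping for relative risks is configuration; the
  default feeds the category-resolved all-ages meta-analysis to every
  stratum, with an age-specific preset shipped as an alternative (the
  source meta-analyses cover inconsistent age ranges, so *any* mapping is
  a compromise).

Because the smoothing model is fitted at area level, stratum-level
compositions are obtained by the same mechanism the generator uses: stratum
odds offsets applied to the drawn area margins, with the intercept
re-solved (vectorized Newton) so the population-weighted stratum mean
reproduces each draw's area margin exactly.

For presentation, attributable deaths are rounded *up* to whole deaths and
reported with the share of total deaths (standardized totals under
scenario 1, crude totals under scenario 2) computed from the unrounded
mean.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

* **Map:** a rook-adjacency grid (or random planar graph) stands in for the
  municipality map; no real geography is reproduced.
* **Population:** area populations are lognormal (median ≈ 9,000 persons
  15+); age, gender and education shares are Dirichlet/normal draws around
  national margins of 34/44/22% (ages 15-39/40-64/65+), 48% male and
  5/12/32/50% across four education levels.
* **Truth:** the logit of each area's current-smoking margin is exactly
  `intercept + covariate effects + b` with `b` drawn from the BYM2 model
  (defaults: national prevalence 19%, modest negative effects of high
  education and age 65+, σ = 0.35, φ = 0.5). Ever smoking fixes
  current/ever at 19/42; heavy/moderate/light split current as 2/10/7. Six
  age-gender strata shift these margins on the odds scale (more smoking in
  men, much less at 65+) while preserving the area margins exactly.
* **Survey:** areas are sampled PPS (large municipalities are effectively
  always in sample), equal-size households of 4 within areas, all members
  of a selected household respond; the respondent target (~50) scales with
  population size, capped at 5x, so realized sample sizes span a few to a
  few hundred — matching the survey being emulated. Household clustering
  adds an intra-cluster correlation of 0.05 on the latent scale.
  Inclusion probabilities are the product of the stage probabilities; the
  operational sampling fractions of the real survey are unpublished, so
  this construction is a documented stand-in. Post-stratification weights
  match the six national age-gender strata exactly.
* **Missingness:** smoking status is missing at random given education —
  23% below tertiary, 16% tertiary, ≈19% overall. (The observed pattern in
  the emulated survey motivates the MAR-given-education mechanism; nothing
  beyond it is invented.)
* **Mortality:** per area-stratum cell, expected deaths are
  `persons x never-smoker rate x mean RR`, counts are Poisson. The
  recorded ground truth is the true attributable *fraction* and the
  attributable share of the deaths that actually occurred
  (`D_obs x PAF_true`), so recovery checks are not polluted by Poisson
  noise in the totals.

What passing tests on these data do **not** show: robustness to informative
missingness (the generator is MAR), to real municipal geography, to
individual-level confounding (covariates act at area level only, so the
generator cannot produce ecological fallacy), or to relative risks that
differ from the packaged ones.

# Numerical choices

* All randomness flows from one master seed through a documented splitting
  helper (`split_seed`); identical configurations reproduce bit-identical
  outputs.
* The joint Gaussian update adds a jitter of 1e-6 x the ICAR diagonal
  scale to keep the Cholesky factorization positive definite; the
  constraints remove the affected directions exactly, so the jitter has no
  practical effect on retained draws.
* Margin-matching intercepts are solved by vectorized Newton iteration to
  1e-10, with probabilities clamped to [1e-6, 1 - 1e-6] before logits.
* Degenerate inputs: all-zero composition draws fall back to
  never-smoker = 1; areas with a single household cluster get zero
  estimated design variance and are flagged degenerate; zero-death areas
  report 0 attributable deaths (0%).
* Validation problem sizes (chosen so the whole suite runs in minutes on
  one CPU, and recorded here as the package's settings): 100-area grids
  with 60 in-sample areas; 50 replicates for interval calibration; 20 for
  the DIC-direction and shrinkage checks; 10 end-to-end replicates for
  attributable-death recovery; MCMC at 1-2 chains x 1,200-1,500
  iterations inside simulations versus the 4 x 5,000 defaults for data
  analysis.

# Limitations

* The logit-normal model for direct estimates is a large-sample
  approximation. For rare categories (heavy smoking, ≈2%) in areas with
  tens of respondents, excluding degenerate (zero-count) areas selects
  upward: the expected logit of a *non-zero* estimate exceeds the true
  logit, which inflates the fitted national level of the rare category.
  The end-to-end recovery test quantifies the consequence: area-level
  attributable-death estimates carry a few percent of upward bias beyond
  their posterior spread. A binomial-likelihood small-area model would
  remove this at the cost of leaving the design-based framework.
* Posterior uncertainty is the dominant error term: under the validation
  design, the posterior coefficient of variation of area SAM is ≈20% for
  the areas that dominate the death counts, so point-estimate errors of
  that order are the information floor of the design, not an
  implementation artifact (the intervals are calibrated: ≈98% of true SAM
  values fall inside their 95% intervals).
* Multiple imputation of missing smoking status is deliberately out of
  scope; estimates are conservative if lower-educated (more often missing)
  respondents smoke more.
* No spatio-temporal extension, no cause-specific mortality, no lag
  between exposure and death.
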