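# smokesae

Small-area estimation of smoking prevalence from complex health-interview
surveys, and the municipal mortality burden it implies.

## The problem

Health interview surveys sample only a fraction of a country's
municipalities (typically about a quarter), with anywhere from a handful to
a few hundred respondents each. Design-based direct estimates of municipal
smoking prevalence are then unavailable for off-sample municipalities and
wildly unstable elsewhere — they can span 0 to 100% through sampling noise
alone. Without municipal prevalence there is no municipal estimate of
smoking-attributable mortality, which is what local prevention policy
needs.

`smokesae` implements the full chain:

1. **Direct estimation** — Hájek (weight-normalized) prevalence per area,
   `p̂_i = Σ w_ik y_ik / Σ w_ik`, with cluster-linearized design variance
   and the delta-method logit transform `V̂_i = var(p̂)/(p̂(1−p̂))²`.
2. **Spatial smoothing** — a Bayesian hierarchical model on the logit
   scale, `logit(p̂_i) ~ N(θ_i, V̂_i)`, `θ_i = x_iᵀβ + b_i`, with a BYM2
   random effect `b = σ(√φ·u* + √(1−φ)·v)` (scaled ICAR `u*` on the
   municipality adjacency graph, iid `v`), a penalized-complexity prior
   `P(σ > 1) = 0.01`, fitted by the package's own MCMC (Gibbs +
   Metropolis-within-Gibbs with interweaving). Off-sample areas borrow
   strength through the graph and covariates. DIC and CPO diagnostics
   included.
3. **Category decomposition** — posterior draws of the nested indicators
   heavy ⊂ heavy+moderate ⊂ current ⊂ ever are differenced draw-by-draw
   into the five-category composition (heavy/moderate/light/former/never),
   clamping negative differences at zero and rescaling each draw to sum
   to 1.
4. **Attributable mortality** — multi-category population attributable
   fraction `PAF = Σ P_j(RR_j−1) / (1 + Σ P_j(RR_j−1))` and attributable
   deaths `SAM_i = D_i × PAF_i`, with Monte-Carlo propagation of 1,000
   posterior composition draws × 1,000 gamma draws of published relative
   risks, under an age-gender standardized scenario and a six-strata
   scenario.
5. **Synthetic data** — a generator with known ground truth emulating the
   survey design (PPS area sampling, household clusters,
   post-stratification weights, education-graded ~19% item missingness,
   spatially correlated true prevalence), used to validate every stage.

## Worked example

```r
library(smokesae)

graph <- generate_adjacency(100, "grid", seed = 1)     # synthetic map
pop   <- generate_population(graph, gen_params(), seed = 2)
svy   <- draw_survey(pop, survey_design(n_insample_areas = 60), seed = 3)
svy
#> survey_microdata: 5632 respondents, 60 areas, 19.7% missing smoking status

direct <- build_direct_table(svy, c("heavy", "moderate", "light"))
round(range(direct$p_hat, na.rm = TRUE), 3)
#> [1] 0.000 0.395            # direct estimates: unusable spread

fit <- fit_bym(direct, pop$areas, graph,
               bym_spec(covariates = c("edu_high", "age65p"),
                        iters = 2000, burnin = 800, chains = 2, seed = 4))
fit
#> bym_fit: 100 areas ( 59 in likelihood ), 2400 posterior draws
#>   posterior mean sigma: 0.277  phi: 0.455
#>   max split-Rhat: 1.009

smoothed <- prevalence_summaries(fit)
round(range(smoothed$mean), 3)
#> [1] 0.122 0.374            # smoothed: strictly inside the direct range
head(smoothed, 3)
#>   area      mean       q025      q975 insample
#> 1 A001 0.1442236 0.08999293 0.2152772     TRUE
#> 2 A002 0.1687300 0.11895017 0.2256386     TRUE
#> 3 A003 0.2351215 0.14057503 0.3461231    FALSE
```

The direct estimates for current smoking span 0–40% across areas; the
smoothed posterior means span 12–37%, every area (including the 40
off-sample ones) gets an estimate with a credible interval, and the
convergence diagnostic is clean. The whole pipeline — four ladder fits,
decomposition, both attributable-mortality scenarios, all tables written
to an output directory — is one call:

```r
cfg <- read_pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "smokesae"),
  seed = 1, outdir = "demo_out")
res <- run_pipeline(cfg)
head(sam_report(res$sam2)[order(-sam_report(res$sam2)$sam_display),
                          c("area", "formatted")], 5)
#>    area          formatted
#> 42 A042 93 [71; 117] (14%)
#> 61 A061 85 [65; 108] (14%)
#> 7  A007  77 [58; 96] (19%)
#> 43 A043  67 [51; 82] (17%)
#> 32 A032  66 [48; 84] (17%)
```

Each line reads: estimated smoking-attributable deaths (rounded up),
best–worst 95% interval, and share of the area's total deaths. At the
national composition (2/10/7/23/58% heavy/moderate/light/former/never)
with the category-resolved meta-analysis relative risks
(2.38/2.02/1.47/1.31), `paf()` returns 0.1895 — about a fifth of all-cause
deaths attributable to smoking.

See `vignette("small-area-smoking")` for the models, priors, sampler,
generator assumptions and limitations.

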