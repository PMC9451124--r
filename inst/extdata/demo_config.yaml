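# Demo pipeline: 100-area synthetic map, paper-mimicking survey design
# (about 60% of areas in-sample, ~50 respondents per area scaled with
# population size), full five-category ladder, both SAM scenarios.
seed: 1
n_areas: 100
layout: grid
design:
  n_insample_areas: 60
  target_per_area: 50
covariates:
  - edu_high
  - age65p
mcmc:
  iters: 1500
  burnin: 500
  chains: 1
rr_study: shavelle2008
rr_mapping: shavelle
n_draws: 1000
verbose: no
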