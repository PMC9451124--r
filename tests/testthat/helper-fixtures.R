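# Small fixtures built in code, shared across test files.

# a direct-estimate table assembled by hand (bypassing survey machinery)
make_direct <- function(area, logit_mean, logit_var) {
  data.frame(area = area, n_obs = 50L, p_hat = plogis(logit_mean),
             var_p = logit_var * (plogis(logit_mean) *
                                    (1 - plogis(logit_mean)))^2,
             logit_mean = logit_mean, logit_var = logit_var,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

# microdata assembled by hand: y (0/1 outcome mapped to current/never),
# weights, cluster ids, all in one area
make_microdata <- function(y, w, cluster = seq_along(y), area = "A001") {
  data.frame(area = area, cluster = cluster,
             age_group = "40-64", gender = "M", education = "edu_high",
             pi = 1 / w, w_design = w, w_post = w,
             smoking = ifelse(y == 1, "light", "never"),
             stringsAsFactors = FALSE)
}

# exact variance of the Hajek ratio under with-replacement resampling of
# clusters from the empirical cluster distribution (all n^n equally likely
# resamples), inflated by n/(n-1) as in the standard with-replacement
# design-variance estimator that the linearization approximates
enumerate_cluster_variance <- function(y, w, cluster) {
  cl <- unique(cluster)
  n <- length(cl)
  tot_wy <- tapply(w * y, cluster, sum)[as.character(cl)]
  tot_w <- tapply(w, cluster, sum)[as.character(cl)]
  grids <- do.call(expand.grid, rep(list(seq_len(n)), n))
  est <- apply(grids, 1, function(pick)
    sum(tot_wy[pick]) / sum(tot_w[pick]))
  n / (n - 1) * mean((est - mean(est))^2)
}

# the generator's true finite-area current-smoking margin for each area
true_current <- function(pop) pop$truth$area$p_current

# quick paper-mimicking simulation: population, survey, direct table
sim_direct <- function(seed, n_areas = 100, n_insample = 60,
                       target = 50, fixed_n = FALSE,
                       beta = c("(Intercept)" = -1.5, edu_high = 0.8),
                       sigma = 0.5, phi = 0.5,
                       outcome = c("heavy", "moderate", "light")) {
  seeds <- smokesae::split_seed(seed, 3)
  g <- generate_adjacency(n_areas, "grid", 1)
  pop <- generate_population(g, gen_params(beta = beta, sigma = sigma,
                                           phi = phi), seeds[1])
  des <- if (fixed_n)
    survey_design(n_insample_areas = n_insample, target_per_area = target,
                  cluster_dispersion = Inf, scale_with_pop = FALSE,
                  missing = FALSE)
  else survey_design(n_insample_areas = n_insample, target_per_area = target)
  md <- draw_survey(pop, des, seeds[2])
  list(graph = g, pop = pop, microdata = md,
       direct = build_direct_table(md, outcome), fit_seed = seeds[3])
}
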