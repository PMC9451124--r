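test_that("Hajek prevalence reproduces weighted-mean arithmetic", {
  md <- make_microdata(y = c(1, 0), w = c(1, 1))
  est <- ht_prevalence(md, "A001", "light")
  expect_equal(est$p_hat, 0.5)

  md2 <- make_microdata(y = c(1, 1, 0, 0), w = c(2, 2, 1, 1))
  expect_equal(ht_prevalence(md2, "A001", "light")$p_hat, 4 / 6)

  # invariance under rescaling all weights
  md3 <- make_microdata(y = c(1, 1, 0, 0), w = 7.3 * c(2, 2, 1, 1))
  e2 <- ht_prevalence(md2, "A001", "light")
  e3 <- ht_prevalence(md3, "A001", "light")
  expect_equal(e2$p_hat, e3$p_hat)
  expect_equal(e2$var_p, e3$var_p, tolerance = 1e-12)
})

test_that("missing outcomes are excluded and no-data areas error", {
  md <- make_microdata(y = c(1, 0, 0), w = c(1, 1, 1))
  md$smoking[3] <- NA
  est <- ht_prevalence(md, "A001", "light")
  expect_equal(est$n_obs, 2L)
  expect_equal(est$p_hat, 0.5)
  md$smoking <- NA_character_
  expect_error(ht_prevalence(md, "A001", "light"), "no respondents")
})

test_that("linearized variance matches enumeration of cluster resamples", {
  # Designs with balanced cluster weight totals make the Hajek ratio exactly
  # linear (agreement is exact); mild imbalance keeps the Taylor error well
  # under the 10% band. (Severe imbalance at n = 2 breaks any linearization
  # of a ratio; that regime is outside what the estimator claims.)
  cases <- list(
    list(y = c(1, 0), w = c(1, 1), cl = c(1, 2)),
    list(y = c(1, 1, 0, 0), w = c(1.1, 1, 1, 0.9), cl = c(1, 1, 2, 2)),
    list(y = c(1, 0, 1, 0, 0, 1), w = c(1, 1.2, 0.9, 1, 1, 1.1),
         cl = c(1, 1, 2, 2, 3, 3)),
    list(y = c(0, 1, 1, 1, 0, 0), w = c(1.5, 1, 1, 1.2, 1, 1.3),
         cl = c(1, 1, 2, 2, 3, 3)))
  exact_first <- c(TRUE, FALSE, FALSE, FALSE)
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    md <- make_microdata(cs$y, cs$w, cluster = cs$cl)
    est <- ht_prevalence(md, "A001", "light")
    # point estimate: exact brute-force weighted mean
    expect_equal(est$p_hat, sum(cs$w * cs$y) / sum(cs$w), tolerance = 1e-12)
    oracle <- enumerate_cluster_variance(cs$y, cs$w, cs$cl)
    tol <- if (exact_first[k]) 1e-9 else 0.10
    expect_equal(est$var_p, oracle, tolerance = tol)
  }
})

test_that("logit transform applies the delta method and rejects degeneracy", {
  est <- make_direct("A001", 0, 1)  # placeholder, overwrite fields
  est$p_hat <- 0.5; est$var_p <- 0.01; est$degenerate <- FALSE
  out <- logit_transform(est)
  expect_equal(out$logit_mean, 0)
  expect_equal(out$logit_var, 0.16)

  est2 <- est; est2$p_hat <- 0.2679; est2$var_p <- 0.001
  out2 <- logit_transform(est2)
  expect_equal(out2$logit_mean, log(0.2679 / 0.7321), tolerance = 1e-6)

  est$var_p <- 0; est$degenerate <- TRUE
  expect_error(logit_transform(est), "degenerate")
})

test_that("a census yields the exact population prevalence with zero variance", {
  g <- generate_adjacency(4, "grid")
  pop <- generate_population(g, gen_params(pop_meanlog = log(250),
                                           pop_sdlog = 0.1), seed = 2)
  md <- draw_survey(pop, survey_design(census = TRUE), seed = 3)
  for (a in unique(md$area)) {
    sub <- md[md$area == a, ]
    truth <- mean(sub$smoking %in% c("heavy", "moderate", "light"))
    est <- ht_prevalence(md, a, c("heavy", "moderate", "light"))
    expect_equal(est$p_hat, truth, tolerance = 1e-9)
  }
})

test_that("direct table covers every sampled area and flags degenerates", {
  md <- rbind(make_microdata(c(1, 1), c(1, 1), area = "A001"),
              make_microdata(c(1, 0, 1), c(1, 2, 1), area = "A002"))
  dt <- build_direct_table(md, "light")
  expect_s3_class(dt, "direct_table")
  expect_equal(nrow(dt), 2)
  expect_true(dt$degenerate[dt$area == "A001"])  # both smokers: p_hat = 1
  expect_false(dt$degenerate[dt$area == "A002"])
  expect_error(build_direct_table(md[0, ], "light"), "empty")

  sim <- sim_direct(77)
  expect_equal(nrow(sim$direct), length(unique(sim$microdata$area)))
})

test_that("direct estimates cover the truth at nominal rates for large n", {
  hits <- 0L; total <- 0L
  for (r in 1:5) {
    g <- generate_adjacency(12, "grid", 1)
    pop <- generate_population(g, gen_params(), seed = 500 + r)
    md <- draw_survey(pop, survey_design(n_insample_areas = 12,
                                         target_per_area = 600,
                                         scale_with_pop = FALSE,
                                         cluster_dispersion = Inf,
                                         missing = FALSE), seed = 600 + r)
    dt <- build_direct_table(md, c("heavy", "moderate", "light"))
    dt <- dt[!dt$degenerate, ]
    tr <- true_current(pop)[match(dt$area, pop$areas$area)]
    hits <- hits + sum(abs(dt$p_hat - tr) <= 3 * sqrt(dt$var_p))
    total <- total + nrow(dt)
  }
  expect_gte(hits / total, 0.97)
})
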