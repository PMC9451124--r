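test_that("without random effects, identical covariates give identical truth", {
  g <- generate_adjacency(16, "grid")
  p0 <- gen_params(beta = c("(Intercept)" = smokesae:::logit(0.2)),
                   sigma = 0)
  pop <- generate_population(g, p0, seed = 5)
  # no covariates in beta and sigma = 0: every area's margin is exactly 0.2
  expect_equal(pop$truth$area$p_current, rep(0.2, 16), tolerance = 1e-12)
  expect_equal(pop$truth$area$b, rep(0, 16))
})

test_that("generated populations satisfy their structural invariants", {
  g <- generate_adjacency(40, "random-planar", seed = 2)
  pop <- generate_population(g, gen_params(), seed = 9)
  a <- pop$areas
  expect_equal(a$age15_39 + a$age40_64 + a$age65p, rep(1, 40),
               tolerance = 1e-9)
  expect_equal(rowSums(as.matrix(a[, c("edu_primary", "edu_lower_sec",
                                       "edu_higher_sec", "edu_high")])),
               rep(1, 40), tolerance = 1e-9)
  st <- aggregate(persons ~ area, pop$strata, sum)
  expect_equal(st$persons[match(a$area, st$area)], a$pop)
  # stratum compositions are simplexes
  cm <- as.matrix(pop$truth$composition[, smokesae:::SMOKING_CATEGORIES])
  expect_true(all(cm >= 0))
  expect_equal(rowSums(cm), rep(1, nrow(cm)), tolerance = 1e-9)
  # the area margin invariant: logit(current margin) = lp + b
  mrg <- merge(pop$truth$composition, pop$strata)
  cur <- with(mrg, heavy + moderate + light)
  agg <- tapply(cur * mrg$persons, mrg$area, sum) /
    tapply(mrg$persons, mrg$area, sum)
  expect_equal(as.numeric(agg[a$area]),
               plogis(pop$truth$area$lp + pop$truth$area$b),
               tolerance = 1e-8)
})

test_that("spatial random effects show positive spatial autocorrelation", {
  g <- generate_adjacency(100, "grid", 1)
  pop <- generate_population(g, gen_params(sigma = 0.5, phi = 1), seed = 21)
  res <- morans_i(pop$truth$area$b, g, n_perm = 499, seed = 1)
  expect_lt(res$p_value, 0.01)
})

test_that("without random effects the logit prevalences are exchangeable", {
  g <- generate_adjacency(49, "grid", 1)
  p0 <- gen_params(beta = c("(Intercept)" = smokesae:::logit(0.2)),
                   sigma = 0, male_sd = 0.03)
  # sigma = 0, no covariates: any apparent spatial signal is noise from the
  # (iid) demographic draws; significant Moran's I should be a rare event
  n_sig <- 0L
  for (r in 1:20) {
    pop <- generate_population(g, p0, seed = 100 + r)
    x <- smokesae:::logit(plogis(pop$truth$area$lp + pop$truth$area$b) +
                            rnorm(49, 0, 1e-6))
    if (morans_i(x, g, n_perm = 199, seed = r)$p_value < 0.01)
      n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("census design reproduces the finite population exactly", {
  g <- generate_adjacency(6, "grid")
  pop <- generate_population(g, gen_params(pop_meanlog = log(300),
                                           pop_sdlog = 0.1), seed = 3)
  md <- draw_survey(pop, survey_design(census = TRUE), seed = 4)
  expect_equal(nrow(md), sum(pop$areas$pop))
  expect_true(all(md$pi == 1))
  expect_true(all(!is.na(md$smoking)))
  # weighted prevalence = unweighted realized prevalence (weights all 1...
  # up to post-stratification, which is a no-op at full enumeration)
  y <- md$smoking %in% c("heavy", "moderate", "light")
  expect_equal(sum(md$w_post * y) / sum(md$w_post), mean(y),
               tolerance = 1e-9)
})

test_that("survey design hits the requested number of in-sample areas", {
  g <- generate_adjacency(300, "grid", 1)
  pop <- generate_population(g, gen_params(), seed = 10)
  md <- draw_survey(pop, survey_design(n_insample_areas = 154,
                                       target_per_area = 20), seed = 2)
  expect_equal(length(unique(md$area)), 154)
  expect_error(draw_survey(pop, survey_design(n_insample_areas = 301)),
               "n_insample_areas")
})

test_that("post-stratified weights reproduce population margins", {
  for (s in 1:3) {
    g <- generate_adjacency(60, "grid", 1)
    pop <- generate_population(g, gen_params(), seed = 30 + s)
    md <- draw_survey(pop, survey_design(n_insample_areas = 25,
                                         target_per_area = 40), seed = 40 + s)
    expect_true(all(md$w_design >= 1))
    got <- aggregate(w_post ~ age_group + gender, md, sum)
    want <- aggregate(persons ~ age_group + gender, pop$strata, sum)
    m <- merge(got, want)
    expect_equal(m$w_post, m$persons, tolerance = 1e-3)
    expect_equal(sum(md$w_post), sum(pop$areas$pop), tolerance = 1e-3)
  }
})

test_that("missingness is ~19% overall and education-graded", {
  g <- generate_adjacency(400, "grid", 1)
  pop <- generate_population(g, gen_params(), seed = 8)
  md <- draw_survey(pop, survey_design(n_insample_areas = 400,
                                       target_per_area = 100,
                                       scale_with_pop = FALSE,
                                       cluster_dispersion = Inf), seed = 6)
  expect_gt(nrow(md), 3e4)
  miss <- is.na(md$smoking)
  expect_equal(mean(miss), 0.19, tolerance = 0.01 / 0.19)  # 19% +/- 1pp
  low <- md$education != "edu_high"
  expect_gt(mean(miss[low]), mean(miss[!low]))
  expect_equal(mean(miss[low]), 0.23, tolerance = 0.015 / 0.23)
  expect_equal(mean(miss[!low]), 0.16, tolerance = 0.015 / 0.16)
})

test_that("mortality counts match their closed-form expectation", {
  g <- generate_adjacency(2, "grid")
  pop <- generate_population(g, gen_params(pop_meanlog = log(20000),
                                           pop_sdlog = 0.05), seed = 12)
  rrset <- load_relative_risks()
  rr <- rr_point_estimates(rrset, "shavelle2008")
  # closed form: lambda = sum over cells of persons * rate * sum_j p_j RR_j
  comp <- merge(pop$truth$composition, pop$strata)
  rr5 <- c(rr, never = 1)
  lam <- with(comp, persons * baseline_rates()[paste(age_group, gender,
                                                     sep = ":")] *
                as.matrix(comp[, names(rr5)]) %*% rr5)
  lam_tot <- sum(lam)
  tot <- vapply(1:400, function(s)
    sum(generate_mortality(pop, rr, seed = s)$deaths), 0)
  expect_equal(mean(tot), lam_tot, tolerance = 0.005)
  # all RR = 1: attributable fraction identically zero
  m0 <- generate_mortality(pop, c(heavy = 1, moderate = 1, light = 1,
                                  former = 1), seed = 1)
  expect_equal(m0$true_paf, rep(0, nrow(m0)))
  expect_equal(m0$true_sam, rep(0, nrow(m0)))
  # with all RR >= 1 the recorded true PAF lies in [0, 1)
  m1 <- generate_mortality(pop, rr, seed = 2)
  expect_true(all(m1$true_paf >= 0 & m1$true_paf < 1))
  expect_true(all(m1$deaths >= 0))
})
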