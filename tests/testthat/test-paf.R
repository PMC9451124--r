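rrset <- load_relative_risks()

test_that("gamma moment matching reproduces published intervals", {
  gm <- fit_gamma_rr(1.83, c(1.65, 2.03))
  expect_equal(gm$sd, 0.38 / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(gm$shape, (1.83 / gm$sd)^2, tolerance = 1e-12)
  expect_equal(gm$shape / gm$rate, 1.83, tolerance = 1e-9)

  expect_equal(fit_gamma_rr(1, c(1, 1))$sd, 0)  # point mass

  set.seed(2)
  x <- rgamma(1e6, gm$shape, gm$rate)
  expect_equal(mean(x), 1.83, tolerance = 0.005)
  expect_equal(quantile(x, 0.025, names = FALSE), 1.65, tolerance = 0.03)
  expect_equal(quantile(x, 0.975, names = FALSE), 2.03, tolerance = 0.03)
})

test_that("every packaged RR row is internally consistent", {
  expect_true(all(rrset$rr > 0))
  expect_true(all(rrset$ci_low <= rrset$rr & rrset$rr <= rrset$ci_high))
  ok <- is.finite(rrset$shape)
  expect_equal(rrset$shape[ok] / rrset$rate[ok], rrset$rr[ok],
               tolerance = 1e-9)
})

test_that("PAF reproduces the multi-category worked value", {
  comp <- c(heavy = 0.02, moderate = 0.10, light = 0.07,
            former = 0.23, never = 0.58)
  rr <- rr_point_estimates(rrset, "shavelle2008")
  expect_equal(rr, c(heavy = 2.38, moderate = 2.02, light = 1.47,
                     former = 1.31))
  expect_equal(paf(comp, rr), 0.1895, tolerance = 1e-3)
  # all RR at 1: nothing attributable
  expect_equal(paf(comp, c(heavy = 1, moderate = 1, light = 1, former = 1)),
               0)
  expect_error(paf(c(0.5, 0.2, 0.1, 0.1, 0.2) * 2, rr), "simplex")
})

test_that("PAF is monotone in RR, approaches 1, and permutes cleanly", {
  comp <- c(heavy = 0.02, moderate = 0.10, light = 0.07,
            former = 0.23, never = 0.58)
  rr <- rr_point_estimates(rrset, "shavelle2008")
  vals <- sapply(c(2.38, 5, 50, 5000), function(r) {
    rr2 <- rr; rr2["heavy"] <- r; paf(comp, rr2)
  })
  expect_true(all(diff(vals) > 0))
  expect_lt(max(vals), 1)
  expect_gt(vals[4], 0.99 * paf(comp, rr) + 0.0)  # tends to 1
  expect_equal(vals[4], 1, tolerance = 0.02)
  # permuting category labels together with their RRs changes nothing
  perm <- c("light", "former", "heavy", "moderate", "never")
  expect_equal(paf(comp[perm], rr[setdiff(perm, "never")]), paf(comp, rr))
  # increasing an exposed category at the expense of never raises PAF
  comp2 <- comp + c(0.05, 0, 0, 0, -0.05)
  expect_gt(paf(comp2, rr), paf(comp, rr))
})

# small stratified fixture shared by the scenario tests
make_sam_fixture <- function(S = 400, areas = c("A1", "A2"), flat = TRUE,
                             seed = 9) {
  sg <- smokesae:::all_strata()
  keys <- smokesae:::stratum_key(sg$age_group, sg$gender)
  set.seed(seed)
  comp <- array(NA_real_, c(S, length(areas), 6, 5),
                dimnames = list(NULL, areas, keys,
                                smokesae:::SMOKING_CATEGORIES))
  for (a in seq_along(areas)) for (s in 1:6) {
    base <- if (flat) c(0.02, 0.10, 0.07, 0.23, 0.58) else {
      x <- abs(rnorm(5)) + 0.2; x / sum(x)
    }
    comp[, a, s, ] <- matrix(base, S, 5, byrow = TRUE)
  }
  deaths <- data.frame(area = rep(areas, each = 6),
                       age_group = rep(sg$age_group, length(areas)),
                       gender = rep(sg$gender, length(areas)),
                       stringsAsFactors = FALSE)
  deaths$persons <- if (flat) 1000L else as.integer(200 + 100 * seq_len(nrow(deaths)))
  deaths$deaths <- if (flat) 10L else as.integer(2 + seq_len(nrow(deaths)))
  deaths$true_paf <- 0; deaths$true_sam <- 0
  list(comp = comp, deaths = deaths, keys = keys)
}

test_that("scenario 1 standardization is a no-op for flat strata", {
  fx <- make_sam_fixture(flat = TRUE)
  est <- sam_scenario1(fx$comp, fx$deaths, std = NULL, rrset,
                       n_draws = 500, seed = 3)
  # flat strata: standardized deaths = crude deaths = 60 per area, and the
  # composition is constant, so SAM = 60 * PAF(base, rr draws)
  expect_equal(est$summary$deaths_total, c(60, 60), tolerance = 1e-9)
  expect_equal(est$summary$sam_mean[1], est$summary$sam_mean[2],
               tolerance = 1e-9)
  rr <- rr_point_estimates(rrset, "shavelle2008")
  det <- 60 * paf(c(heavy = 0.02, moderate = 0.10, light = 0.07,
                    former = 0.23, never = 0.58), rr)
  expect_equal(est$summary$sam_mean[1], det, tolerance = 0.02)
})

test_that("constant PAF gives exact SAM with zero-width intervals", {
  fx <- make_sam_fixture(flat = TRUE)
  rr1 <- rrset
  rr1[rr1$study == "shavelle2008", c("rr", "ci_low", "ci_high")] <-
    rep(c(2, 2, 2), each = 4)
  rr1$shape[rr1$study == "shavelle2008"] <- Inf
  est <- sam_scenario1(fx$comp, fx$deaths, std = NULL, rr1,
                       n_draws = 300, seed = 1)
  p_const <- paf(c(heavy = 0.02, moderate = 0.10, light = 0.07,
                   former = 0.23, never = 0.58),
                 c(heavy = 2, moderate = 2, light = 2, former = 2))
  expect_equal(est$summary$sam_mean, rep(60 * p_const, 2), tolerance = 1e-9)
  expect_equal(est$summary$sam_q025, est$summary$sam_q975, tolerance = 1e-9)
})

test_that("scenario 2 is additive over strata and matches pooled computation", {
  fx <- make_sam_fixture(flat = TRUE)
  est2 <- sam_scenario2(fx$comp, fx$deaths, rrset, n_draws = 400, seed = 7)
  # identical compositions and one RR set: stratum sum = pooled computation
  est1 <- sam_scenario1(fx$comp, fx$deaths, std = NULL, rrset,
                        n_draws = 400, seed = 7)
  expect_equal(est2$summary$sam_mean, est1$summary$sam_mean,
               tolerance = 1e-9)
  # additivity holds draw by draw: recompute one stratum's share
  fx1 <- fx
  fx1$deaths$deaths[fx1$deaths$age_group != "65+"] <- 0L
  fx2 <- fx
  fx2$deaths$deaths[fx2$deaths$age_group == "65+"] <- 0L
  e1 <- sam_scenario2(fx1$comp, fx1$deaths, rrset, n_draws = 400, seed = 7)
  e2 <- sam_scenario2(fx2$comp, fx2$deaths, rrset, n_draws = 400, seed = 7)
  expect_equal(e1$draws + e2$draws, est2$draws, tolerance = 1e-9)
  # a stratum with RR = 1 contributes nothing
  rr1 <- rrset
  rr1[rr1$study == "shavelle2008", c("rr", "ci_low", "ci_high")] <- 1
  rr1$shape[rr1$study == "shavelle2008"] <- Inf
  e0 <- sam_scenario2(fx$comp, fx$deaths, rr1, n_draws = 100, seed = 2)
  expect_equal(as.vector(e0$draws), rep(0, 200))
  # unmapped stratum is a configuration error
  expect_error(sam_scenario2(fx$comp, fx$deaths, rrset,
                             mapping = c("15-39:F" = "shavelle2008"),
                             n_draws = 100, seed = 1),
               "no RR study mapped")
})

test_that("the report rounds up and computes shares of total deaths", {
  est <- structure(list(summary = data.frame(
    area = c("A1", "A2"), paf_mean = c(0.2, 0),
    sam_mean = c(4.2, 0), sam_q025 = c(4.2, 0), sam_q975 = c(4.2, 0),
    deaths_total = c(21, 0), scenario = 1L),
    draws = matrix(c(4.2, 0), 1, 2, dimnames = list(NULL, c("A1", "A2"))),
    scenario = 1L), class = "sam_estimate")
  rep <- sam_report(est)
  expect_equal(rep$sam_display, c(5, 0))
  expect_equal(rep$pct_of_deaths, c(20, 0))
  expect_match(rep$formatted[1], "5 \\[5; 5\\] \\(20%\\)")
})

test_that("disaggregation preserves the area margins it was given", {
  g <- generate_adjacency(12, "grid")
  pop <- generate_population(g, gen_params(), seed = 4)
  S <- 150
  set.seed(8)
  draws <- matrix(plogis(rnorm(S * 12, -1.3, 0.3)), S, 12,
                  dimnames = list(NULL, g$area_ids))
  comp <- assemble_composition(
    list(0.1 * draws, 0.6 * draws, draws, pmin(draws * 2.2, 0.98)))
  cs <- disaggregate_composition(comp, pop)
  # population-weighted stratum current margins reproduce each draw's area
  # current margin
  stw <- with(pop$strata, tapply(persons, list(area, paste(age_group, gender,
                                                           sep = ":")), sum))
  stw <- stw[g$area_ids, dimnames(cs)[[3]]] / rowSums(stw[g$area_ids, ])
  cur_st <- cs[, , , "heavy"] + cs[, , , "moderate"] + cs[, , , "light"]
  cur_area <- comp[, , "heavy"] + comp[, , "moderate"] + comp[, , "light"]
  for (a in c(1L, 7L)) {
    got <- cur_st[, a, ] %*% stw[a, ]
    expect_equal(as.numeric(got), as.numeric(cur_area[, a]),
                 tolerance = 1e-6)
  }
  # stratum simplexes remain simplexes
  tot <- apply(cs, c(1, 2, 3), sum)
  expect_equal(range(tot), c(1, 1), tolerance = 1e-9)
  expect_true(all(cs >= -1e-12))
})
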