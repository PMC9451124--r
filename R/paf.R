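#' Moment-matched gamma distribution for a relative risk
#'
#' Converts a published relative-risk point estimate with 95% confidence
#' interval into gamma parameters: the CI width is read as a symmetric
#' normal interval, `sd = (high - low) / (2 * 1.96)`, then
#' `shape = (point/sd)^2`, `rate = shape/point`, so the gamma mean equals
#' the point estimate exactly. A zero-width CI yields a point mass
#' (`shape = Inf`), which downstream samplers treat as degenerate.
#'
#' @param point RR point estimate (> 0).
#' @param ci numeric length-2 vector `(low, high)` with
#'   `0 < low <= point <= high`.
#' @return list with `shape`, `rate`, `sd`.
#' @export
fit_gamma_rr <- function(point, ci) {
  low <- ci[1]; high <- ci[2]
  if (!(low > 0 && low <= point && point <= high))
    stop("need 0 < low <= point <= high")
  s <- (high - low) / (2 * stats::qnorm(0.975))
  if (s == 0) return(list(shape = Inf, rate = Inf, sd = 0))
  shape <- (point / s)^2
  list(shape = shape, rate = shape / point, sd = s)
}

#' Load the packaged relative-risk table
#'
#' Reads the relative risks for all-cause mortality from smoking extracted
#' from four published meta-analyses (per exposure category: point estimate
#' and 95% CI), and fits the gamma distribution used for Monte-Carlo
#' propagation to each row.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data frame of class `relative_risk_set` with columns `study`,
#'   `region`, `gender`, `ages`, `category`, `rr`, `ci_low`, `ci_high`,
#'   `shape`, `rate`.
#' @export
load_relative_risks <- function(path = system.file("extdata",
                                                   "relative_risks.csv",
                                                   package = "smokesae")) {
  rr <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(rr$rr > 0), all(rr$ci_low <= rr$rr), all(rr$rr <= rr$ci_high))
  g <- Map(fit_gamma_rr, rr$rr, Map(c, rr$ci_low, rr$ci_high))
  rr$shape <- vapply(g, `[[`, 0, "shape")
  rr$rate <- vapply(g, `[[`, 0, "rate")
  class(rr) <- c("relative_risk_set", "data.frame")
  rr
}

#' Resolve one study's relative risks for the four smoking categories
#'
#' Maps a study's published exposure categories onto the package's
#' `heavy/moderate/light/former` ladder (never is the reference, RR = 1).
#' Studies that report a single "current smoker" RR contribute it to all
#' three current categories; the 40-59-year cohort study reports light and
#' ">= 10 cigarettes/day" (used for moderate and heavy) but no former-smoker
#' RR, which is borrowed from the 60+ meta-analysis. These fallbacks are
#' deliberate and documented — the source meta-analyses do not cover all
#' categories at all ages.
#'
#' @param rrset a `relative_risk_set`.
#' @param study one of `"shavelle2008"`, `"gellert2012"`, `"carter2015"`,
#'   `"jacobs1999"`.
#' @param gender `"M"` or `"F"` (only consulted where the study is
#'   gender-specific).
#' @return data frame with rows heavy, moderate, light, former and columns
#'   `rr`, `shape`, `rate`.
#' @export
rr_for_study <- function(rrset, study, gender = "M") {
  pick <- function(st, cat, gen = NULL) {
    sel <- rrset$study == st & rrset$category == cat
    if (!is.null(gen) && sum(sel) > 1) sel <- sel & rrset$gender == gen
    if (!any(sel)) stop("no RR for study ", st, " category ", cat)
    rrset[which(sel)[1], c("rr", "shape", "rate")]
  }
  rows <- switch(study,
    shavelle2008 = list(pick("shavelle2008", "heavy"),
                        pick("shavelle2008", "moderate"),
                        pick("shavelle2008", "light"),
                        pick("shavelle2008", "former")),
    gellert2012 = list(pick("gellert2012", "current"),
                       pick("gellert2012", "current"),
                       pick("gellert2012", "current"),
                       pick("gellert2012", "former")),
    carter2015 = list(pick("carter2015", "current", gender),
                      pick("carter2015", "current", gender),
                      pick("carter2015", "current", gender),
                      pick("gellert2012", "former")),
    jacobs1999 = list(pick("jacobs1999", "smoker10plus"),
                      pick("jacobs1999", "smoker10plus"),
                      pick("jacobs1999", "light"),
                      pick("gellert2012", "former")),
    stop("unknown study: ", study))
  out <- do.call(rbind, rows)
  rownames(out) <- c("heavy", "moderate", "light", "former")
  out
}

#' Point-estimate relative risks of one study
#' @inheritParams rr_for_study
#' @return named numeric vector over heavy, moderate, light, former.
#' @export
rr_point_estimates <- function(rrset, study = "shavelle2008", gender = "M") {
  tab <- rr_for_study(rrset, study, gender)
  stats::setNames(tab$rr, rownames(tab))
}

# n gamma draws of the four category RRs of one study: n x 4 matrix
draw_rr <- function(rrset, study, n, gender = "M") {
  tab <- rr_for_study(rrset, study, gender)
  m <- vapply(seq_len(4), function(j) {
    if (!is.finite(tab$shape[j])) rep(tab$rr[j], n)
    else stats::rgamma(n, shape = tab$shape[j], rate = tab$rate[j])
  }, numeric(n))
  colnames(m) <- rownames(tab)
  m
}

#' Stratum-to-study mapping presets for the six-strata scenario
#'
#' `"shavelle"` (default) uses the all-ages, category-resolved meta-analysis
#' for every stratum. `"age_specific"` maps the working-age strata to the
#' 40-59-year cohort pooling and the 65+ strata to the 60+ meta-analysis;
#' the source meta-analyses cover inconsistent age ranges, so any mapping
#' involves compromise.
#'
#' @param preset `"shavelle"` or `"age_specific"`.
#' @return named character vector: stratum key -> study id.
#' @export
rr_stratum_mapping <- function(preset = c("shavelle", "age_specific")) {
  preset <- match.arg(preset)
  sg <- all_strata()
  keys <- stratum_key(sg$age_group, sg$gender)
  if (preset == "shavelle")
    return(stats::setNames(rep("shavelle2008", length(keys)), keys))
  stats::setNames(ifelse(sg$age_group == "65+", "gellert2012", "jacobs1999"),
                  keys)
}

#' Population attributable fraction for multi-category exposure
#'
#' Levin's formula for several exposure categories
#' `PAF = sum_j P_j (RR_j - 1) / (1 + sum_j P_j (RR_j - 1))`, where the sum
#' runs over the exposed categories and never smokers are the reference
#' (RR = 1). The denominator equals `sum_j P_j RR_j` taken over all
#' categories including the reference, which keeps PAF in `[0, 1)` whenever
#' all RR >= 1.
#'
#' @param composition numeric simplex over the five smoking categories
#'   (named, or ordered heavy/moderate/light/former/never).
#' @param rr named relative risks for `heavy`, `moderate`, `light`,
#'   `former`.
#' @return scalar PAF.
#' @export
paf <- function(composition, rr) {
  if (length(composition) != 5 || any(composition < -1e-12) ||
      abs(sum(composition) - 1) > 1e-6)
    stop("composition must be a 5-category simplex")
  if (is.null(names(composition))) names(composition) <- SMOKING_CATEGORIES
  ex <- setdiff(SMOKING_CATEGORIES, "never")
  s <- sum(composition[ex] * (rr[ex] - 1))
  as.numeric(s / (1 + s))
}

# vectorized PAF: P is m x 5 (category columns), rr is m x 4 or length-4
paf_mat <- function(P, rr) {
  ex <- c("heavy", "moderate", "light", "former")
  if (is.null(dim(rr))) rr <- matrix(rr[ex], nrow(P), 4, byrow = TRUE,
                                     dimnames = list(NULL, ex))
  s <- rowSums(P[, ex, drop = FALSE] * (rr[, ex, drop = FALSE] - 1))
  s / (1 + s)
}

#' Disaggregate area-level composition draws into age-gender strata
#'
#' Mirrors the generative model's stratum structure: for each posterior
#' draw, the area's current and ever margins are shifted by the configured
#' stratum odds offsets, with the intercepts re-solved so the
#' population-weighted stratum means reproduce the drawn area margins
#' exactly; heavy/moderate/light keep the draw's conditional split within
#' current smoking.
#'
#' @param comp a `category_composition` (draw x area x 5 array).
#' @param pop an `area_population` providing stratum person counts.
#' @param offsets named stratum logit offsets, defaulting to the
#'   generator's.
#' @return 4-d array (draw, area, stratum, category); stratum names are
#'   `"15-39:F"` etc.
#' @export
disaggregate_composition <- function(comp, pop,
                                     offsets = gen_params()$stratum_offsets) {
  S <- dim(comp)[1]; ar <- dimnames(comp)[[2]]; A <- length(ar)
  sg <- all_strata()
  keys <- stratum_key(sg$age_group, sg$gender)
  st <- pop$strata
  stw <- matrix(0, A, 6, dimnames = list(ar, keys))
  for (s in seq_len(6)) {
    sel <- st$age_group == sg$age_group[s] & st$gender == sg$gender[s]
    stw[st$area[sel], s] <- st$persons[sel]
  }
  stw <- stw / rowSums(stw)

  cl <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  cur <- cl(comp[, , "heavy"] + comp[, , "moderate"] + comp[, , "light"])
  ev <- cl(pmax(cur, cur + comp[, , "former"]))
  # units = draw-area pairs; weights constant across draws of one area
  wts <- stw[rep(seq_len(A), each = S), , drop = FALSE]
  offm <- matrix(offsets[keys], S * A, 6, byrow = TRUE)
  a_cur <- solve_margin_intercept(as.vector(cur), offm, wts)
  a_ev <- solve_margin_intercept(as.vector(ev), offm, wts)
  pc <- expit(a_cur + offm)
  pe <- pmax(expit(a_ev + offm), pc)

  out <- array(NA_real_, c(S, A, 6, 5),
               dimnames = list(NULL, ar, keys, SMOKING_CATEGORIES))
  frac <- function(cat) as.vector(comp[, , cat]) / as.vector(cur)
  for (s in seq_len(6)) {
    out[, , s, "heavy"] <- pc[, s] * frac("heavy")
    out[, , s, "moderate"] <- pc[, s] * frac("moderate")
    out[, , s, "light"] <- pc[, s] * frac("light")
    out[, , s, "former"] <- pe[, s] - pc[, s]
    out[, , s, "never"] <- 1 - pe[, s]
  }
  out
}

# align a mortality table into A x 6 matrices of deaths and persons
mortality_matrices <- function(deaths, areas, strata_keys) {
  D <- N <- matrix(0, length(areas), 6, dimnames = list(areas, strata_keys))
  k <- stratum_key(deaths$age_group, deaths$gender)
  for (r in seq_len(nrow(deaths))) {
    a <- deaths$area[r]
    if (a %in% areas) {
      D[a, k[r]] <- D[a, k[r]] + deaths$deaths[r]
      N[a, k[r]] <- N[a, k[r]] + deaths$persons[r]
    }
  }
  list(D = D, N = N)
}

sam_summarize <- function(sam_draws, paf_draws, totals, scenario) {
  data.frame(
    area = colnames(sam_draws),
    paf_mean = colMeans(paf_draws),
    sam_mean = colMeans(sam_draws),
    sam_q025 = apply(sam_draws, 2, stats::quantile, 0.025, names = FALSE),
    sam_q975 = apply(sam_draws, 2, stats::quantile, 0.975, names = FALSE),
    deaths_total = totals,
    scenario = scenario,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Smoking-attributable mortality, standardized scenario
#'
#' Scenario 1: both the smoking composition and the death counts of every
#' area are directly standardized to a standard population's age-gender
#' stratum shares before the attributable fraction is applied, removing
#' differences in demographic structure between areas. Per Monte-Carlo
#' draw, one posterior composition draw and one gamma draw of the relative
#' risks are combined; `SAM = D_std x PAF`.
#'
#' @param comp_strata 4-d stratum composition array from
#'   [disaggregate_composition()].
#' @param deaths a `mortality_table` (area x stratum death counts and
#'   person counts).
#' @param std named standard-population shares over the six strata (summing
#'   to 1), e.g. the national population; defaults to the person-weighted
#'   shares in `deaths`.
#' @param rrset a `relative_risk_set`.
#' @param study RR source study for all strata.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed integer seed; prevalence and RR streams are split from it.
#' @return object of class `sam_estimate`: `summary` data frame (per area:
#'   mean PAF, mean/2.5%/97.5% SAM, standardized total deaths) and the SAM
#'   draw matrix.
#' @export
sam_scenario1 <- function(comp_strata, deaths, std = NULL, rrset,
                          study = "shavelle2008", n_draws = 1000, seed = 1L) {
  S <- dim(comp_strata)[1]; ar <- dimnames(comp_strata)[[2]]
  keys <- dimnames(comp_strata)[[3]]
  mm <- mortality_matrices(deaths, ar, keys)
  if (any(rowSums(mm$N) == 0)) stop("missing stratum rows for some areas")
  if (is.null(std)) {
    std <- colSums(mm$N) / sum(mm$N)
  }
  std <- std[keys]
  stopifnot(abs(sum(std) - 1) < 1e-6)

  seeds <- split_seed(seed, 2)
  set.seed(seeds[1])
  idx <- if (S >= n_draws) sample.int(S, n_draws) else
    sample.int(S, n_draws, replace = TRUE)
  set.seed(seeds[2])  # independent stream for the relative risks
  rr <- draw_rr(rrset, study, n_draws)

  # standardized composition: weighted average of stratum simplexes
  comp_std <- array(0, c(n_draws, length(ar), 5),
                    dimnames = list(NULL, ar, SMOKING_CATEGORIES))
  for (s in seq_along(keys)) {
    slab <- comp_strata[idx, , s, , drop = FALSE]
    dim(slab) <- c(n_draws, length(ar), 5)
    comp_std <- comp_std + std[s] * slab
  }
  # standardized death counts: area population times standardized rate
  rate <- mm$D / pmax(mm$N, 1)
  d_std <- rowSums(mm$N) * as.numeric(rate %*% std)

  paf_draws <- sapply(seq_along(ar), function(a)
    paf_mat(comp_std[, a, ], rr))
  colnames(paf_draws) <- ar
  sam_draws <- sweep(paf_draws, 2, d_std, "*")
  structure(list(summary = sam_summarize(sam_draws, paf_draws, d_std, 1L),
                 draws = sam_draws, scenario = 1L),
            class = "sam_estimate")
}

#' Smoking-attributable mortality, six-strata scenario
#'
#' Scenario 2: the attributable fraction is computed within each of the six
#' age-gender strata with the stratum's own crude death count, then summed
#' to the area total per Monte-Carlo draw. A stratum-to-study mapping
#' selects which meta-analysis feeds each stratum's relative risks.
#'
#' @inheritParams sam_scenario1
#' @param mapping named character vector stratum key -> study id, e.g. from
#'   [rr_stratum_mapping()]. Every stratum present in the composition must
#'   be mapped.
#' @return a `sam_estimate` (with per-area crude total deaths).
#' @export
sam_scenario2 <- function(comp_strata, deaths, rrset,
                          mapping = rr_stratum_mapping("shavelle"),
                          n_draws = 1000, seed = 1L) {
  S <- dim(comp_strata)[1]; ar <- dimnames(comp_strata)[[2]]
  keys <- dimnames(comp_strata)[[3]]
  unmapped <- setdiff(keys, names(mapping))
  if (length(unmapped))
    stop("no RR study mapped for stratum ", paste(unmapped, collapse = ", "))
  mm <- mortality_matrices(deaths, ar, keys)

  seeds <- split_seed(seed, 2)
  set.seed(seeds[1])
  idx <- if (S >= n_draws) sample.int(S, n_draws) else
    sample.int(S, n_draws, replace = TRUE)
  set.seed(seeds[2])
  studies <- unique(mapping[keys])
  rr_by_study <- lapply(stats::setNames(studies, studies), function(st)
    draw_rr(rrset, st, n_draws))

  sam_draws <- matrix(0, n_draws, length(ar), dimnames = list(NULL, ar))
  paf_num <- matrix(0, n_draws, length(ar), dimnames = list(NULL, ar))
  for (s in seq_along(keys)) {
    rr <- rr_by_study[[mapping[keys[s]]]]
    for (a in seq_along(ar)) {
      pafs <- paf_mat(comp_strata[idx, a, s, ], rr)
      sam_draws[, a] <- sam_draws[, a] + mm$D[a, s] * pafs
      paf_num[, a] <- paf_num[, a] + mm$D[a, s] * pafs
    }
  }
  tot <- rowSums(mm$D)
  paf_draws <- sweep(paf_num, 2, pmax(tot, 1), "/")
  structure(list(summary = sam_summarize(sam_draws, paf_draws, tot, 2L),
                 draws = sam_draws, scenario = 2L),
            class = "sam_estimate")
}

#' @export
print.sam_estimate <- function(x, ...) {
  cat("sam_estimate (scenario ", x$scenario, "): ", ncol(x$draws),
      " areas, ", nrow(x$draws), " draws\n", sep = "")
  cat("  attributable share of deaths: ",
      sprintf("%.0f%%-%.0f%%",
              100 * min(x$summary$sam_mean / pmax(x$summary$deaths_total, 1)),
              100 * max(x$summary$sam_mean / pmax(x$summary$deaths_total, 1))),
      "\n", sep = "")
  invisible(x)
}

#' Presentation table of attributable deaths per area
#'
#' Formats a `sam_estimate` the way such results are reported: attributable
#' death counts rounded up to whole deaths, the 95% interval as a
#' best-worst range, and the share of the area's total deaths (standardized
#' totals under scenario 1, crude under scenario 2) from the unrounded
#' mean.
#'
#' @param est a `sam_estimate`.
#' @return data frame: `area`, `sam_display` (ceiling of the mean),
#'   `lo_display`, `hi_display`, `pct_of_deaths`, `formatted`.
#' @export
sam_report <- function(est) {
  s <- est$summary
  pct <- ifelse(s$deaths_total > 0, 100 * s$sam_mean / s$deaths_total, 0)
  data.frame(
    area = s$area,
    sam_display = ceiling(s$sam_mean),
    lo_display = ceiling(s$sam_q025),
    hi_display = ceiling(s$sam_q975),
    pct_of_deaths = pct,
    formatted = sprintf("%d [%d; %d] (%.0f%%)", ceiling(s$sam_mean),
                        ceiling(s$sam_q025), ceiling(s$sam_q975), pct),
    row.names = NULL, stringsAsFactors = FALSE)
}
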