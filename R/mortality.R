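#' Default never-smoker all-cause death rates per age-gender stratum
#'
#' Annual baseline (never-smoker) death probabilities loosely modeled on
#' Western European all-cause mortality: negligible below 40, then rising
#' steeply with age and higher in men.
#'
#' @return named numeric vector over the six strata.
#' @export
baseline_rates <- function() {
  c("15-39:M" = 0.0008, "15-39:F" = 0.0004,
    "40-64:M" = 0.0040, "40-64:F" = 0.0025,
    "65+:M"   = 0.0450, "65+:F"   = 0.0350)
}

#' Generate stratified death counts with recoverable ground truth
#'
#' Forward model consistent with the attributable-fraction machinery: in
#' each area-stratum cell the expected number of deaths is
#' `persons * rate_never * sum_j p_j RR_j` (never smokers have RR = 1) and
#' observed counts are Poisson. The recorded ground truth per cell is the
#' true attributable fraction (Levin formula on the true composition) and
#' the true attributable deaths `D_obs * PAF_true`, i.e. the attributable
#' share of the deaths that actually occurred, so that downstream recovery
#' checks are not polluted by Poisson noise in the death totals.
#'
#' @param pop an `area_population`.
#' @param rr named relative risks for `heavy`, `moderate`, `light`,
#'   `former` (never is implicitly 1), e.g. from
#'   `rr_point_estimates(load_relative_risks(), "shavelle2008")`.
#' @param rates named per-stratum never-smoker death rates,
#'   default [baseline_rates()].
#' @param seed integer seed.
#' @return data frame of class `mortality_table`: `area`, `age_group`,
#'   `gender`, `persons`, `deaths`, `true_paf`, `true_sam`.
#' @export
generate_mortality <- function(pop, rr, rates = baseline_rates(), seed = 1L) {
  stopifnot(inherits(pop, "area_population"), all(rates >= 0))
  rr <- rr[c("heavy", "moderate", "light", "former")]
  stopifnot(!anyNA(rr), all(rr > 0))
  comp <- pop$truth$composition
  st <- pop$strata
  key_c <- paste(comp$area, comp$age_group, comp$gender)
  key_s <- paste(st$area, st$age_group, st$gender)
  comp <- comp[match(key_s, key_c), ]

  rr5 <- c(rr, never = 1)
  P <- as.matrix(comp[, SMOKING_CATEGORIES])
  mean_rr <- as.numeric(P %*% rr5[SMOKING_CATEGORIES])
  excess <- as.numeric(P %*% (rr5[SMOKING_CATEGORIES] - 1))
  paf_true <- excess / (1 + excess)
  rate <- rates[stratum_key(st$age_group, st$gender)]
  lambda <- st$persons * rate * mean_rr
  set.seed(split_seed(seed, 1))
  deaths <- stats::rpois(length(lambda), lambda)

  out <- data.frame(area = st$area, age_group = st$age_group,
                    gender = st$gender, persons = st$persons,
                    deaths = as.integer(deaths),
                    true_paf = paf_true,
                    true_sam = deaths * paf_true,
                    stringsAsFactors = FALSE)
  class(out) <- c("mortality_table", "data.frame")
  out
}

#' Area-level totals of a mortality table
#' @param deaths a `mortality_table`.
#' @return data frame with `area`, `deaths`, `true_sam`, `true_paf`
#'   (deaths-weighted).
#' @export
mortality_totals <- function(deaths) {
  agg <- stats::aggregate(cbind(deaths, true_sam) ~ area,
                          as.data.frame(deaths), sum)
  agg$true_paf <- ifelse(agg$deaths > 0, agg$true_sam / agg$deaths, 0)
  agg
}
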