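#' Default generative settings for the synthetic population
#'
#' The defaults emulate the national margins of the 2018 Belgian health
#' interview survey population: age 15+ split roughly 34/44/22% across
#' 15-39 / 40-64 / 65+, 48% male, education shares 5/12/32/50%, and a
#' national smoking composition of about 2% heavy, 10% moderate, 7% light,
#' 23% former and 58% never smokers (current 19%, ever 42%).
#'
#' @param beta named numeric vector of fixed effects on the logit of current
#'   smoking; the first element is the intercept, remaining names must be
#'   area-covariate columns (standardized across areas, see
#'   [area_design_matrix()]).
#' @param sigma total standard deviation of the area random effect (>= 0).
#' @param phi spatial mixing fraction in `[0,1]` (1 = purely structured ICAR).
#' @param current_given_ever conditional probability of being a current
#'   smoker given ever smoking (controls the former-smoker margin).
#' @param current_split conditional split of current smokers into
#'   heavy/moderate/light.
#' @param stratum_offsets named logit offsets of current/ever smoking for the
#'   six age-gender strata (names `"15-39:M"` etc.); encode that smoking is
#'   more common in men and less common at ages 65+.
#' @param pop_meanlog,pop_sdlog lognormal parameters for area population
#'   sizes (persons aged 15+).
#' @param age_conc,edu_conc Dirichlet concentration of area age and
#'   education shares around the national margins.
#' @param male_sd standard deviation of the area male share around 0.48.
#' @return list of generative settings for [generate_population()].
#' @export
gen_params <- function(beta = c("(Intercept)" = logit(0.19),
                                edu_high = -0.25, age65p = -0.15),
                       sigma = 0.35, phi = 0.5,
                       current_given_ever = 19 / 42,
                       current_split = c(heavy = 2, moderate = 10, light = 7) / 19,
                       stratum_offsets = c("15-39:M" = 0.35, "15-39:F" = 0.05,
                                           "40-64:M" = 0.30, "40-64:F" = 0.10,
                                           "65+:M" = -0.55, "65+:F" = -0.85),
                       pop_meanlog = log(9000), pop_sdlog = 0.8,
                       age_conc = 80, edu_conc = 60, male_sd = 0.015) {
  stopifnot(sigma >= 0, phi >= 0, phi <= 1,
            current_given_ever > 0, current_given_ever < 1,
            abs(sum(current_split) - 1) < 1e-9)
  list(beta = beta, sigma = sigma, phi = phi,
       current_given_ever = current_given_ever,
       current_split = current_split,
       stratum_offsets = stratum_offsets,
       pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
       age_conc = age_conc, edu_conc = edu_conc, male_sd = male_sd)
}

rdirichlet1 <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

# one draw of b = sigma * (sqrt(phi) u* + sqrt(1-phi) v), with u* a scaled
# ICAR draw constrained to sum to zero within each connected component
draw_bym_effect <- function(graph, sigma, phi) {
  n <- n_areas(graph)
  if (sigma == 0) return(rep(0, n))
  v <- stats::rnorm(n)
  u <- rep(0, n)
  if (phi > 0) {
    comps <- graph_components(graph)$membership
    sc <- scale_icar(graph)
    W <- adjacency_matrix(graph)
    Q <- diag(rowSums(W)) - W
    for (cc in unique(comps)) {
      idx <- which(comps == cc)
      if (length(idx) == 1L) next  # singleton: structured part defined as 0
      Qc <- Q[idx, idx, drop = FALSE] * sc[as.character(cc)]
      e <- eigen(Qc, symmetric = TRUE)
      pos <- e$values > max(e$values) * 1e-9
      # sample from N(0, Qc^+) restricted to the non-null eigenspace
      z <- stats::rnorm(sum(pos)) / sqrt(e$values[pos])
      u[idx] <- e$vectors[, pos, drop = FALSE] %*% z
    }
  }
  as.numeric(sigma * (sqrt(phi) * u + sqrt(1 - phi) * v))
}

#' Generate a synthetic area population with known smoking ground truth
#'
#' Draws per-area population sizes, age/gender/education structure, and true
#' five-category smoking compositions per age-gender stratum. The logit of
#' each area's current-smoking margin is, by construction, exactly the
#' covariate linear predictor plus the BYM2 random effect
#' `b = sigma (sqrt(phi) u* + sqrt(1-phi) v)`; stratum-level probabilities
#' are obtained by shifting that margin with the configured stratum odds
#' offsets and re-solving the intercept so the population-weighted stratum
#' mean reproduces the area margin exactly.
#'
#' @param graph an `adjacency_graph`.
#' @param params settings from [gen_params()].
#' @param seed integer seed.
#' @return list with components `areas` (data frame: area, pop, covariate
#'   shares), `strata` (long data frame: area, age_group, gender, persons),
#'   and `truth` (list: area-level data frame with `lp`, `b`, `p_current`,
#'   `p_ever`; stratum-level composition data frame; the generating
#'   parameters and design matrix).
#' @export
generate_population <- function(graph, params = gen_params(), seed = 1L) {
  seeds <- split_seed(seed, 3)
  ids <- graph$area_ids
  n <- length(ids)

  set.seed(seeds[1])
  pop <- pmax(200L, as.integer(round(stats::rlnorm(n, params$pop_meanlog,
                                                   params$pop_sdlog))))
  age <- rdirichlet1(n, params$age_conc * c(0.34, 0.44, 0.22))
  edu <- rdirichlet1(n, params$edu_conc * c(0.05, 0.12, 0.32, 0.50))
  male <- pmin(0.65, pmax(0.35, stats::rnorm(n, 0.48, params$male_sd)))
  areas <- data.frame(area = ids, pop = pop,
                      age15_39 = age[, 1], age40_64 = age[, 2],
                      age65p = age[, 3], male = male,
                      edu_primary = edu[, 1], edu_lower_sec = edu[, 2],
                      edu_higher_sec = edu[, 3], edu_high = edu[, 4],
                      stringsAsFactors = FALSE)

  # integer stratum counts that sum exactly to the area total
  sg <- all_strata()
  strata <- do.call(rbind, lapply(seq_len(n), function(i) {
    sh_age <- c("15-39" = age[i, 1], "40-64" = age[i, 2], "65+" = age[i, 3])
    sh_g <- c(M = male[i], F = 1 - male[i])
    w <- sh_age[sg$age_group] * sh_g[sg$gender]
    cnt <- floor(pop[i] * w)
    rem <- pop[i] - sum(cnt)
    if (rem > 0) {
      extra <- order(pop[i] * w - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    data.frame(area = ids[i], age_group = sg$age_group, gender = sg$gender,
               persons = as.integer(cnt), stringsAsFactors = FALSE)
  }))

  covars <- setdiff(names(params$beta), "(Intercept)")
  X <- area_design_matrix(areas, covars)
  beta <- params$beta[colnames(X)]
  lp <- as.numeric(X %*% beta)

  set.seed(seeds[2])
  b <- draw_bym_effect(graph, params$sigma, params$phi)
  p_cur <- expit(lp + b)
  p_ever <- pmin(p_cur / params$current_given_ever, 0.98)

  # stratum-level compositions matching both area margins exactly
  off <- params$stratum_offsets[stratum_key(sg$age_group, sg$gender)]
  wts <- matrix(strata$persons, n, 6, byrow = TRUE) /
    matrix(pop, n, 6)
  offm <- matrix(off, n, 6, byrow = TRUE)
  a_cur <- solve_margin_intercept(p_cur, offm, wts)
  a_ev <- solve_margin_intercept(p_ever, offm, wts)
  pc_s <- expit(a_cur + offm)  # n x 6 current by stratum
  pe_s <- pmax(expit(a_ev + offm), pc_s)  # ever >= current
  split <- params$current_split
  comp <- data.frame(
    area = rep(ids, each = 6),
    age_group = rep(sg$age_group, n),
    gender = rep(sg$gender, n),
    heavy = as.numeric(t(pc_s)) * split["heavy"],
    moderate = as.numeric(t(pc_s)) * split["moderate"],
    light = as.numeric(t(pc_s)) * split["light"],
    former = as.numeric(t(pe_s - pc_s)),
    never = as.numeric(t(1 - pe_s)),
    stringsAsFactors = FALSE)

  truth <- list(
    area = data.frame(area = ids, lp = lp, b = b, p_current = p_cur,
                      p_ever = p_ever, stringsAsFactors = FALSE),
    composition = comp,
    params = params, X = X,
    alpha_current = a_cur, alpha_ever = a_ev)
  structure(list(areas = areas, strata = strata, truth = truth),
            class = "area_population")
}

#' @export
print.area_population <- function(x, ...) {
  cat("area_population:", nrow(x$areas), "areas,",
      format(sum(x$areas$pop), big.mark = ","), "persons 15+\n")
  cat("  true current-smoking margin:",
      sprintf("%.3f-%.3f", min(x$truth$area$p_current),
              max(x$truth$area$p_current)), "\n")
  invisible(x)
}
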