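#' Survey design settings for the synthetic sampler
#'
#' Defaults emulate the health-interview-survey design the package targets:
#' about a quarter of the areas are in-sample (selected with probability
#' proportional to population size, as large cities are effectively always
#' sampled), households of a few persons are drawn within each sampled area
#' until a target of roughly 50 respondents, and item missingness on smoking
#' status is education-dependent (about 23% below tertiary education versus
#' 16% with tertiary education, around 19% overall).
#'
#' @param n_insample_areas number of areas to sample.
#' @param target_per_area expected number of respondents per sampled area.
#' @param persons_per_cluster household (cluster) size.
#' @param cluster_dispersion negative-binomial size parameter controlling the
#'   residual spread of realized per-area sample sizes around their target;
#'   `Inf` gives a fixed number of clusters per area.
#' @param scale_with_pop logical; if `TRUE` (default), an area's respondent
#'   target scales with its population (capped at `pop_scale_cap` times the
#'   base target), emulating how large cities receive several interview
#'   groups — the survey being emulated ranged from 2 to 249 respondents
#'   per municipality, with the large counts in the large municipalities.
#' @param pop_scale_cap cap on the population scaling factor.
#' @param pps logical; sample areas with probability proportional to size.
#' @param icc intra-cluster correlation of smoking on the latent logistic
#'   scale (household members are more alike than strangers).
#' @param missing_prob named per-education-level probabilities that smoking
#'   status is missing; `missing = FALSE` disables missingness.
#' @param missing logical; generate item missingness at all.
#' @param census logical; if `TRUE`, enumerate every person of every area
#'   with inclusion probability 1 and no missingness.
#' @return list of design settings for [draw_survey()].
#' @export
survey_design <- function(n_insample_areas = 154, target_per_area = 50,
                          persons_per_cluster = 4, cluster_dispersion = 6,
                          scale_with_pop = TRUE, pop_scale_cap = 5,
                          pps = TRUE, icc = 0.05,
                          missing_prob = c(edu_primary = 0.23,
                                           edu_lower_sec = 0.23,
                                           edu_higher_sec = 0.23,
                                           edu_high = 0.16),
                          missing = TRUE, census = FALSE) {
  stopifnot(icc >= 0, icc < 1, persons_per_cluster >= 1)
  list(n_insample_areas = n_insample_areas,
       target_per_area = target_per_area,
       persons_per_cluster = persons_per_cluster,
       cluster_dispersion = cluster_dispersion,
       scale_with_pop = scale_with_pop, pop_scale_cap = pop_scale_cap,
       pps = pps, icc = icc, missing_prob = missing_prob,
       missing = missing, census = census)
}

# inclusion probabilities for PPS sampling of n areas, capped at 1 and
# rescaled so they sum to n (standard capping iteration)
pps_inclusion <- function(sizes, n) {
  p <- n * sizes / sum(sizes)
  repeat {
    over <- p >= 1
    if (!any(over) || all(over)) break
    p[over] <- 1
    rest <- !over
    p[rest] <- (n - sum(over)) * sizes[rest] / sum(sizes[rest])
    if (all(p <= 1 + 1e-12)) break
  }
  pmin(p, 1)
}

# systematic PPS sampling achieving the given inclusion probabilities
systematic_pps <- function(pi) {
  ord <- sample.int(length(pi))
  cum <- cumsum(pi[ord])
  u <- stats::runif(1)
  hits <- findInterval(seq(u, sum(pi), by = 1), c(0, cum), left.open = TRUE)
  sort(ord[unique(pmin(hits + 0L, length(pi)))])
}

# vectorized category draw: per respondent, shift the current and ever
# margins by the cluster effect `e` on the logit scale, then draw one of the
# five categories
sample_categories <- function(cur, ev, e, split) {
  cl <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  cur2 <- expit(logit(cl(cur)) + e)
  ev2 <- pmax(expit(logit(cl(ev)) + e), cur2)
  u <- stats::runif(length(cur))
  br <- cbind(cur2 * split[["heavy"]],
              cur2 * (split[["heavy"]] + split[["moderate"]]),
              cur2, ev2)
  idx <- 1L + (u > br[, 1]) + (u > br[, 2]) + (u > br[, 3]) + (u > br[, 4])
  SMOKING_CATEGORIES[idx]
}

#' Draw a clustered, weighted survey sample from a synthetic population
#'
#' Three-stage emulation of a stratified multistage clustered survey: areas
#' are sampled (PPS or simple random), equal-size household clusters are
#' sampled within areas, and all members of a selected household respond.
#' Inclusion probabilities are the product of the stage-wise selection
#' probabilities; design weights are their inverses. Post-stratification
#' weights rescale the design weights within the six national age-gender
#' strata so that weighted stratum totals match the simulated population
#' exactly. Smoking status is set missing with education-dependent
#' probability (missing at random given education).
#'
#' The stage-wise inclusion probabilities are a stand-in for the (unpublished)
#' operational sampling fractions of the survey being emulated; they are
#' internally consistent, which is what the design-based estimators need.
#'
#' @param pop an `area_population` from [generate_population()].
#' @param design settings from [survey_design()].
#' @param seed integer seed.
#' @return data frame of class `survey_microdata`: one row per respondent
#'   with `area`, `cluster`, `age_group`, `gender`, `education`, `pi`
#'   (inclusion probability), `w_design`, `w_post`, `smoking` (category or
#'   `NA` = item missing).
#' @export
draw_survey <- function(pop, design = survey_design(), seed = 1L) {
  stopifnot(inherits(pop, "area_population"))
  areas <- pop$areas
  nA <- nrow(areas)
  seeds <- split_seed(seed, 4)
  comp <- pop$truth$composition
  split <- pop$truth$params$current_split
  key <- paste(comp$area, comp$age_group, comp$gender)
  comp_mat <- as.matrix(comp[, SMOKING_CATEGORIES])
  rownames(comp_mat) <- key

  if (isTRUE(design$census)) {
    sampled <- seq_len(nA)
    pi_area <- rep(1, nA)
  } else {
    m <- design$n_insample_areas
    if (m > nA) stop("n_insample_areas exceeds the number of areas")
    if (!design$census && design$target_per_area > min(areas$pop))
      stop("target_per_area exceeds the population of the smallest area")
    set.seed(seeds[1])
    if (design$pps) {
      pi_all <- pps_inclusion(areas$pop, m)
      sampled <- systematic_pps(pi_all)
      pi_area <- pi_all
    } else {
      sampled <- sort(sample.int(nA, m))
      pi_area <- rep(m / nA, nA)
    }
  }

  set.seed(seeds[2])
  sig_c <- if (design$icc > 0)
    sqrt(design$icc / (1 - design$icc) * pi^2 / 3) else 0
  rows <- vector("list", length(sampled))
  cl_id <- 0L
  for (jj in seq_along(sampled)) {
    i <- sampled[jj]
    aid <- areas$area[i]
    h <- design$persons_per_cluster
    M_i <- max(1L, floor(areas$pop[i] / h))  # households in the area
    if (isTRUE(design$census)) {
      m_i <- M_i
      n_resp <- areas$pop[i]
      pi_cl <- 1
    } else {
      size_fac <- if (isTRUE(design$scale_with_pop))
        min(max(areas$pop[i] / stats::median(areas$pop), 1),
            design$pop_scale_cap) else 1
      mu_cl <- max(design$target_per_area * size_fac / h, 1)
      m_i <- if (is.finite(design$cluster_dispersion))
        1L + stats::rnbinom(1, size = design$cluster_dispersion,
                            mu = mu_cl - 1)
      else as.integer(round(mu_cl))
      m_i <- min(m_i, M_i)
      n_resp <- m_i * h
      pi_cl <- m_i / M_i
    }
    st <- pop$strata[pop$strata$area == aid, ]
    p_strat <- st$persons / sum(st$persons)
    eshare <- as.numeric(areas[i, EDU_LEVELS])
    sidx <- if (isTRUE(design$census))
      sample(rep(seq_len(6), times = st$persons))  # exact enumeration
    else sample(seq_len(6), n_resp, replace = TRUE, prob = p_strat)
    edu <- sample(EDU_LEVELS, n_resp, replace = TRUE, prob = eshare)
    clus <- cl_id + rep(seq_len(if (isTRUE(design$census)) ceiling(n_resp / h)
                                else m_i), each = h, length.out = n_resp)
    cl_id <- max(clus)
    ce <- stats::rnorm(max(clus), 0, sig_c)
    k <- paste(aid, st$age_group[sidx], st$gender[sidx])
    p5 <- comp_mat[k, , drop = FALSE]
    cur <- p5[, "heavy"] + p5[, "moderate"] + p5[, "light"]
    ev <- cur + p5[, "former"]
    e <- if (isTRUE(design$census)) rep(0, n_resp) else ce[clus]
    smoking <- sample_categories(cur, ev, e, split)
    rows[[jj]] <- data.frame(
      area = aid, cluster = clus,
      age_group = st$age_group[sidx], gender = st$gender[sidx],
      education = edu,
      pi = pi_area[i] * pi_cl,
      smoking = smoking, stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  md$w_design <- 1 / md$pi

  # post-stratification to the six national age-gender strata
  pop_tot <- stats::aggregate(persons ~ age_group + gender, pop$strata, sum)
  md$w_post <- md$w_design
  for (r in seq_len(nrow(pop_tot))) {
    sel <- md$age_group == pop_tot$age_group[r] &
      md$gender == pop_tot$gender[r]
    if (any(sel))
      md$w_post[sel] <- md$w_design[sel] *
        pop_tot$persons[r] / sum(md$w_design[sel])
  }

  if (design$missing && !isTRUE(design$census)) {
    set.seed(seeds[3])
    pm <- design$missing_prob[md$education]
    md$smoking[stats::runif(nrow(md)) < pm] <- NA_character_
  }
  rownames(md) <- NULL
  class(md) <- c("survey_microdata", "data.frame")
  md
}

#' @export
print.survey_microdata <- function(x, ...) {
  cat("survey_microdata:", nrow(x), "respondents,",
      length(unique(x$area)), "areas,",
      sprintf("%.1f%% missing smoking status\n", 100 * mean(is.na(x$smoking))))
  invisible(as.data.frame(x))
}
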