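#' Design-based direct prevalence estimate for one area
#'
#' Computes the weight-normalized (Hajek ratio) prevalence
#' `sum(w y) / sum(w)` over the area's respondents with observed smoking
#' status, together with its design variance by cluster-level Taylor
#' linearization of the ratio (clusters = households, with-replacement
#' first-stage approximation, standard for small sampling fractions).
#'
#' Although inverse-probability estimators are often written as the
#' unnormalized weighted total, a prevalence requires the normalized ratio
#' form; that is what is implemented here.
#'
#' @param microdata a `survey_microdata` data frame.
#' @param area area id.
#' @param outcome_def character vector of smoking categories counted as the
#'   event, e.g. `c("heavy","moderate","light")` for current smoking.
#' @param weights `"poststrat"` (default, survey practice) or `"design"`.
#' @return one-row data frame: `area`, `n_obs`, `p_hat`, `var_p`,
#'   `logit_mean`, `logit_var`, `degenerate`. Logit fields are `NA` until
#'   [logit_transform()] is applied (done automatically unless degenerate).
#' @export
ht_prevalence <- function(microdata, area, outcome_def,
                          weights = c("poststrat", "design")) {
  weights <- match.arg(weights)
  sub <- microdata[microdata$area == area & !is.na(microdata$smoking), ,
                   drop = FALSE]
  if (!nrow(sub))
    stop("no respondents with observed smoking status in area ", area)
  w <- if (weights == "poststrat") sub$w_post else sub$w_design
  y <- as.numeric(sub$smoking %in% outcome_def)
  W <- sum(w)
  p <- sum(w * y) / W

  # cluster-level linearization of the ratio
  z <- w * (y - p) / W
  zc <- tapply(z, sub$cluster, sum)
  nc <- length(zc)
  var_p <- if (nc >= 2) nc / (nc - 1) * sum(zc^2) else 0

  est <- data.frame(area = area, n_obs = nrow(sub), p_hat = p, var_p = var_p,
                    logit_mean = NA_real_, logit_var = NA_real_,
                    degenerate = (p <= 0 || p >= 1 || var_p <= 0),
                    stringsAsFactors = FALSE)
  if (!est$degenerate) est <- logit_transform(est)
  est
}

#' Delta-method logit transform of a direct estimate
#'
#' Populates `logit_mean = log(p/(1-p))` and
#' `logit_var = var_p / (p(1-p))^2`, the asymptotic variance on the logit
#' scale, which is the likelihood input of the smoothing model.
#'
#' @param est one-row (or multi-row) direct-estimate data frame.
#' @return the input with logit fields filled in.
#' @export
logit_transform <- function(est) {
  if (any(est$degenerate))
    stop("degenerate estimate (p in {0,1} or zero variance): ",
         "logit transform undefined")
  est$logit_mean <- logit(est$p_hat)
  est$logit_var <- est$var_p / (est$p_hat * (1 - est$p_hat))^2
  est
}

#' Direct-estimate table over all sampled areas
#'
#' One row per area present in the microdata. Areas where the estimate is
#' degenerate (prevalence exactly 0 or 1, or zero design variance — typical
#' for areas with a handful of respondents) are flagged, not dropped: the
#' smoothing model excludes them from the likelihood and imputes them like
#' off-sample areas. Respondents with missing smoking status never enter
#' the estimates.
#'
#' @inheritParams ht_prevalence
#' @return data frame of class `direct_table` with one row per sampled area.
#' @export
build_direct_table <- function(microdata, outcome_def,
                               weights = c("poststrat", "design")) {
  if (!nrow(microdata)) stop("empty microdata")
  weights <- match.arg(weights)
  areas <- sort(unique(microdata$area))
  rows <- lapply(areas, function(a) {
    sub_ok <- any(microdata$area == a & !is.na(microdata$smoking))
    if (!sub_ok)
      return(data.frame(area = a, n_obs = 0L, p_hat = NA_real_,
                        var_p = NA_real_, logit_mean = NA_real_,
                        logit_var = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    ht_prevalence(microdata, a, outcome_def, weights)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("direct_table", "data.frame")
  out
}
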