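#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Stages that need independent random streams draw child seeds from this
#' helper so that the whole pipeline is reproducible bit-for-bit while the
#' stages stay statistically independent.
#'
#' @param seed master seed (non-negative integer).
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Area-level design matrix for prevalence models
#'
#' Builds the fixed-effect design matrix used both by the synthetic-data
#' generator and by [fit_bym()], so that simulated and fitted linear
#' predictors refer to the same covariate coding. Covariate columns are
#' standardized (mean 0, sd 1 across areas); an intercept column is always
#' included.
#'
#' @param areas data frame with one row per area (e.g. `pop$areas` from
#'   [generate_population()]).
#' @param covariates character vector of column names; may be empty
#'   (intercept-only model).
#' @return numeric matrix with rownames = area ids, first column
#'   `(Intercept)`.
#' @export
area_design_matrix <- function(areas, covariates = character()) {
  stopifnot(is.data.frame(areas), "area" %in% names(areas))
  X <- matrix(1, nrow(areas), 1L, dimnames = list(areas$area, "(Intercept)"))
  for (v in covariates) {
    if (!v %in% names(areas)) stop("covariate column not found: ", v)
    x <- areas[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1  # constant column: keep centered zeros
    X <- cbind(X, (x - mean(x)) / s)
    colnames(X)[ncol(X)] <- v
  }
  X
}

# canonical category labels, most to least intense
SMOKING_CATEGORIES <- c("heavy", "moderate", "light", "former", "never")

# the six age-by-gender strata used for standardization and mortality
AGE_GROUPS <- c("15-39", "40-64", "65+")
GENDERS <- c("M", "F")
EDU_LEVELS <- c("edu_primary", "edu_lower_sec", "edu_higher_sec", "edu_high")

stratum_key <- function(age_group, gender) paste(age_group, gender, sep = ":")

all_strata <- function() {
  g <- expand.grid(age_group = AGE_GROUPS, gender = GENDERS,
                   stringsAsFactors = FALSE)
  g[order(g$age_group, g$gender), , drop = FALSE]
}

#' Solve logit intercepts so stratum-weighted prevalence matches a margin
#'
#' Given stratum odds offsets `off_s` and stratum weights `w_s` (summing to 1
#' per unit), finds `alpha` such that `sum_s w_s expit(alpha + off_s) = p`.
#' Vectorized over units (areas, or area-by-draw combinations); used by the
#' generator to impose its area-margin invariant exactly and by the
#' composition disaggregator to mirror it.
#'
#' @param p target margins, vector in (0,1).
#' @param offsets matrix (units x strata) of logit offsets.
#' @param weights matrix (units x strata) of stratum weights, rows sum to 1.
#' @param tol convergence tolerance on the margin.
#' @return vector of intercepts `alpha`.
#' @export
solve_margin_intercept <- function(p, offsets, weights, tol = 1e-10) {
  stopifnot(all(p > 0 & p < 1), nrow(offsets) == length(p),
            all(dim(offsets) == dim(weights)))
  alpha <- logit(p)  # exact when offsets are all zero
  for (it in 1:50) {
    eta <- alpha + offsets
    mu <- expit(eta)
    f <- rowSums(weights * mu) - p
    if (max(abs(f)) < tol) break
    d <- rowSums(weights * mu * (1 - mu))
    d[d < 1e-12] <- 1e-12
    alpha <- alpha - f / d
  }
  alpha
}
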