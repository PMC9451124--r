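#' Clamped difference of two nested indicator draws
#'
#' Given paired posterior draws of a broader binary indicator (e.g. ever
#' smoking) and an indicator nested inside it (e.g. current smoking),
#' returns the per-draw difference (e.g. former smoking), with negative
#' differences — possible because the two indicators are fitted as separate
#' models — clamped to zero.
#'
#' @param p_outer_draws,p_inner_draws numeric matrices (draws x areas) with
#'   identical dimensions and area columns, paired by draw index.
#' @return matrix of clamped differences.
#' @export
decompose_pair <- function(p_outer_draws, p_inner_draws) {
  if (!all(dim(p_outer_draws) == dim(p_inner_draws)))
    stop("draw arrays are misaligned (different dimensions)")
  if (!is.null(colnames(p_outer_draws)) && !is.null(colnames(p_inner_draws)) &&
      !identical(colnames(p_outer_draws), colnames(p_inner_draws)))
    stop("draw arrays are misaligned (different area columns)")
  pmax(p_outer_draws - p_inner_draws, 0)
}

#' Assemble the full smoking composition from nested binary fits
#'
#' Takes posterior draws for a nested ladder of binary indicators —
#' by default heavy, heavy+moderate, current (= heavy+moderate+light) and
#' ever (= current+former) smoking — and converts them draw-by-draw into a
#' composition over the categories by successive differencing down the
#' ladder. Each difference is clamped at zero, the complement of the last
#' ladder rung gives the final category (never smoking), and every draw's
#' category vector is rescaled to sum to exactly 1.
#'
#' @param fits list of `bym_fit` objects or (draws x areas) probability
#'   matrices, ordered from the innermost to the outermost indicator; all
#'   must share areas and draw count, with draws paired by index (shared
#'   seeds).
#' @param categories character vector of `length(fits) + 1` category names,
#'   innermost difference first, complement category last. Default is the
#'   five-category smoking ladder.
#' @return object of class `category_composition`: 3-d array
#'   (draw, area, category) of simplex draws.
#' @export
assemble_composition <- function(fits,
                                 categories = SMOKING_CATEGORIES) {
  mats <- lapply(fits, function(f) if (inherits(f, "bym_fit")) f$draws$p else f)
  if (length(categories) != length(mats) + 1L)
    stop("need length(fits) + 1 category names")
  d1 <- dim(mats[[1]])
  ar <- colnames(mats[[1]])
  for (m in mats) {
    if (!all(dim(m) == d1)) stop("fits have inconsistent draw dimensions")
    if (!identical(colnames(m), ar)) stop("fits have inconsistent area sets")
  }
  S <- d1[1]; A <- d1[2]; K <- length(categories)
  comp <- array(NA_real_, c(S, A, K), dimnames = list(NULL, ar, categories))
  comp[, , 1] <- mats[[1]]
  if (length(mats) > 1)
    for (j in 2:length(mats))
      comp[, , j] <- decompose_pair(mats[[j]], mats[[j - 1]])
  comp[, , K] <- pmax(1 - mats[[length(mats)]], 0)
  tot <- apply(comp, c(1, 2), sum)
  tot[tot <= 0] <- 1  # all-zero draw (cannot happen unless inner=0, outer=1)
  comp <- comp / as.vector(tot)  # recycles over the category slab
  class(comp) <- c("category_composition", class(comp))
  comp
}

#' Posterior summaries of a category composition
#'
#' Per-area, per-category posterior mean and equal-tailed 95% interval.
#' After clamping, the category means need not sum exactly to 1 across a
#' row of the summary table (each draw does).
#'
#' @param comp a `category_composition` (needs at least 100 draws).
#' @return data frame: `area`, `category`, `mean`, `q025`, `q975`.
#' @export
composition_summaries <- function(comp) {
  if (dim(comp)[1] < 100)
    stop("need at least 100 draws for interval summaries")
  ar <- dimnames(comp)[[2]]; cats <- dimnames(comp)[[3]]
  out <- expand.grid(area = ar, category = cats, stringsAsFactors = FALSE)
  out$mean <- as.vector(apply(comp, c(2, 3), mean))
  out$q025 <- as.vector(apply(comp, c(2, 3), stats::quantile, 0.025,
                              names = FALSE))
  out$q975 <- as.vector(apply(comp, c(2, 3), stats::quantile, 0.975,
                              names = FALSE))
  out <- out[order(match(out$area, ar), match(out$category, cats)), ]
  rownames(out) <- NULL
  out
}
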