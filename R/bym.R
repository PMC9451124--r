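#' Model specification for the BYM2 smoothing model
#'
#' The smoothing model treats the logit-scale direct estimate of each
#' non-degenerate in-sample area as Gaussian around the area's linear
#' predictor with known variance (the delta-method design variance):
#' `logit_mean_i ~ N(theta_i, V_i)`, `theta_i = x_i' beta + b_i`, and
#' `b = sigma (sqrt(phi) u* + sqrt(1-phi) v)` with `u*` the scaled ICAR
#' (structured) component and `v` iid standard normal (unstructured). The
#' total random-effect scale `sigma` carries a penalized-complexity prior,
#' the exponential with rate `-log(alpha)/u` (so `P(sigma > u) = alpha`);
#' the mixing fraction `phi` is uniform on `[0,1]` by default.
#'
#' @param covariates character vector of area-covariate column names
#'   (standardized internally); empty for the intercept-only model.
#' @param u,alpha PC-prior parameters for `sigma`: `P(sigma > u) = alpha`.
#'   Defaults `u = 1`, `alpha = 0.01`.
#' @param iters,burnin,thin,chains MCMC settings (per chain).
#' @param seed master seed for the sampler.
#' @param beta_prec prior precision of the (zero-mean Gaussian) fixed
#'   effects.
#' @param sigma_fixed optional fixed value for `sigma` (0 reduces the model
#'   to Bayesian weighted regression on the logits).
#' @param phi_fixed optional fixed value for `phi`.
#' @param rhat_threshold split-chain scale-reduction threshold above which a
#'   convergence warning is emitted.
#' @return list of class `bym_spec`.
#' @export
bym_spec <- function(covariates = character(), u = 1, alpha = 0.01,
                     iters = 5000, burnin = 2000, thin = 1, chains = 4,
                     seed = 1L, beta_prec = 1e-3,
                     sigma_fixed = NULL, phi_fixed = NULL,
                     rhat_threshold = 1.05) {
  stopifnot(u > 0, alpha > 0, alpha < 1, iters > burnin, thin >= 1,
            chains >= 1, beta_prec > 0)
  if (!is.null(sigma_fixed)) stopifnot(sigma_fixed >= 0)
  if (!is.null(phi_fixed)) stopifnot(phi_fixed >= 0, phi_fixed <= 1)
  structure(list(covariates = covariates, u = u, alpha = alpha,
                 iters = iters, burnin = burnin, thin = thin,
                 chains = chains, seed = seed, beta_prec = beta_prec,
                 sigma_fixed = sigma_fixed, phi_fixed = phi_fixed,
                 rhat_threshold = rhat_threshold),
            class = "bym_spec")
}

# split-chain potential scale reduction factor
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(d) {
    h <- length(d) %/% 2
    list(d[seq_len(h)], d[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  if (nn < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- nn * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' Fit the BYM2 smoothing model by MCMC
#'
#' Gibbs sampling with Gaussian full conditionals for the fixed effects and
#' both random-effect components jointly (the per-component sum-to-zero
#' constraints are imposed exactly by conditioning), and random-walk
#' Metropolis updates for `(sigma, phi)` in the non-centered
#' parameterization, interwoven with a centered-parameterization update of
#' `sigma` (ancillarity-sufficiency interweaving) for good mixing at all
#' signal-to-noise ratios. Off-sample areas and areas with degenerate direct
#' estimates contribute nothing to the likelihood; their linear predictors
#' are still sampled, borrowing strength from neighboring areas and the
#' covariates.
#'
#' @param direct a `direct_table` from [build_direct_table()] (need not
#'   cover all areas of the graph).
#' @param covariates data frame with one row per graph area (e.g.
#'   `pop$areas`) holding the covariate columns named in `spec$covariates`.
#' @param graph an `adjacency_graph` covering all areas.
#' @param spec a `bym_spec`.
#' @return object of class `bym_fit`: area ids, in-sample/likelihood flags,
#'   posterior draws (`beta`, `sigma`, `phi`, `b`, `theta`, `p`), the
#'   likelihood inputs (`y`, `V`), split-chain Rhat values, and acceptance
#'   rates.
#' @export
fit_bym <- function(direct, covariates, graph, spec = bym_spec()) {
  ids <- graph$area_ids
  n <- length(ids)
  stopifnot(all(ids %in% covariates$area))
  covariates <- covariates[match(ids, covariates$area), , drop = FALSE]
  X <- area_design_matrix(covariates, spec$covariates)
  p <- ncol(X)

  y_full <- rep(NA_real_, n); V_full <- rep(NA_real_, n)
  dd <- direct[!direct$degenerate & !is.na(direct$logit_var), , drop = FALSE]
  midx <- match(dd$area, ids)
  if (anyNA(midx)) stop("direct estimates refer to areas absent from graph")
  y_full[midx] <- dd$logit_mean
  V_full[midx] <- dd$logit_var
  used <- !is.na(y_full)
  if (sum(used) < 5)
    warning("fewer than 5 non-degenerate in-sample areas; ",
            "posterior will be prior-dominated")

  str <- icar_structure(graph)
  Qs <- str$Qs
  C <- str$C
  k <- nrow(C)
  eQ <- eigen(Qs, symmetric = TRUE)          # for the centered sigma step
  lam <- pmax(eQ$values, 0)
  lam_inv <- ifelse(lam > max(lam, 1) * 1e-9, 1 / lam, 0)

  vinv <- ifelse(used, 1 / V_full, 0)
  y0 <- ifelse(used, y_full, 0)
  XtD <- t(X * vinv)                         # p x n
  XtDX <- XtD %*% X
  XtDy <- as.numeric(XtD %*% y0)
  lambda_pc <- -log(spec$alpha) / spec$u
  eps <- 1e-6 * max(c(diag(Qs)[diag(Qs) > 0], 1))

  n_keep <- (spec$iters - spec$burnin) %/% spec$thin
  S <- n_keep * spec$chains
  res <- list(beta = matrix(NA_real_, S, p, dimnames = list(NULL, colnames(X))),
              sigma = numeric(S), phi = numeric(S),
              u = matrix(NA_real_, S, n, dimnames = list(NULL, ids)),
              b = matrix(NA_real_, S, n, dimnames = list(NULL, ids)),
              theta = matrix(NA_real_, S, n, dimnames = list(NULL, ids)))
  chain_seeds <- split_seed(spec$seed, spec$chains)
  accept <- c(noncentered = 0, centered = 0)
  n_att <- c(noncentered = 0, centered = 0)
  zi_u <- p + seq_len(n)
  zi_v <- p + n + seq_len(n)
  Cz <- matrix(0, k, p + 2 * n)
  Cz[, zi_u] <- C

  loglik_nc <- function(sig, ph, beta, u, v) {
    th <- as.numeric(X %*% beta) + sig * (sqrt(ph) * u + sqrt(1 - ph) * v)
    -0.5 * sum(vinv[used] * (y0[used] - th[used])^2)
  }

  for (ch in seq_len(spec$chains)) {
    set.seed(chain_seeds[ch])
    sigma <- if (!is.null(spec$sigma_fixed)) spec$sigma_fixed
             else stats::runif(1, 0.1, 0.5)
    phi <- if (!is.null(spec$phi_fixed)) spec$phi_fixed
           else stats::runif(1, 0.2, 0.8)
    beta <- tryCatch(
      as.numeric(solve(XtDX + diag(spec$beta_prec + 1e-8, p), XtDy)),
      error = function(e) rep(0, p))
    u <- rep(0, n); v <- rep(0, n)
    ls1 <- log(0.3); ls2 <- log(0.8)  # adaptive RW scales

    for (it in seq_len(spec$iters)) {
      a <- sigma * sqrt(phi)
      cc <- sigma * sqrt(1 - phi)

      ## joint Gaussian update of z = (beta, u, v) | sigma, phi
      P <- matrix(0, p + 2 * n, p + 2 * n)
      P[seq_len(p), seq_len(p)] <- XtDX + diag(spec$beta_prec, p)
      P[seq_len(p), zi_u] <- a * XtD
      P[zi_u, seq_len(p)] <- t(a * XtD)
      P[seq_len(p), zi_v] <- cc * XtD
      P[zi_v, seq_len(p)] <- t(cc * XtD)
      P[zi_u, zi_u] <- Qs + diag(a^2 * vinv + eps, n)
      P[zi_v, zi_v] <- diag(1 + cc^2 * vinv, n)
      duv <- a * cc * vinv
      P[cbind(zi_u, zi_v)] <- duv
      P[cbind(zi_v, zi_u)] <- duv
      r <- c(XtDy, a * vinv * y0, cc * vinv * y0)
      R <- chol(P)
      mu <- backsolve(R, backsolve(R, r, transpose = TRUE))
      z <- mu + backsolve(R, stats::rnorm(p + 2 * n))
      # condition on the sum-to-zero / singleton constraints exactly
      Vc <- backsolve(R, backsolve(R, t(Cz), transpose = TRUE))
      z <- z - Vc %*% solve(Cz %*% Vc, Cz %*% z)
      beta <- z[seq_len(p)]; u <- z[zi_u]; v <- z[zi_v]

      ## non-centered joint RW-MH on (log sigma, logit phi)
      if (is.null(spec$sigma_fixed) || is.null(spec$phi_fixed)) {
        lp_cur <- stats::qlogis(min(max(phi, 1e-12), 1 - 1e-12))
        sig_new <- if (is.null(spec$sigma_fixed))
          exp(log(sigma) + exp(ls1) * stats::rnorm(1)) else sigma
        phi_new <- if (is.null(spec$phi_fixed))
          stats::plogis(lp_cur + exp(ls2) * stats::rnorm(1)) else phi
        logr <- loglik_nc(sig_new, phi_new, beta, u, v) -
          loglik_nc(sigma, phi, beta, u, v)
        if (is.null(spec$sigma_fixed))
          logr <- logr + (-lambda_pc * sig_new + log(sig_new)) -
            (-lambda_pc * sigma + log(sigma))
        if (is.null(spec$phi_fixed))
          logr <- logr + (log(phi_new) + log(1 - phi_new)) -
            (log(phi) + log(1 - phi))
        acc <- is.finite(logr) && log(stats::runif(1)) < logr
        if (acc) { sigma <- sig_new; phi <- phi_new }
        if (it <= spec$burnin) {
          g <- min(0.1, 3 / sqrt(it))
          ls1 <- ls1 + g * (acc - 0.35)
          ls2 <- ls2 + g * (acc - 0.35)
        } else {
          n_att["noncentered"] <- n_att["noncentered"] + 1
          accept["noncentered"] <- accept["noncentered"] + acc
        }
      }

      ## interweaving: centered update of sigma given b = a u + (1-.) v
      if (is.null(spec$sigma_fixed) && sigma > 0) {
        if (it > spec$burnin) n_att["centered"] <- n_att["centered"] + 1
        b <- sigma * (sqrt(phi) * u + sqrt(1 - phi) * v)
        tb <- as.numeric(crossprod(eQ$vectors, b))
        dvec <- phi * lam_inv + (1 - phi)
        q <- sum(tb^2 / dvec)
        lcur <- log(sigma)
        lnew <- lcur + 0.4 * stats::rnorm(1)
        sn <- exp(lnew)
        logr <- (-n * lnew - q / (2 * sn^2) - lambda_pc * sn + lnew) -
          (-n * lcur - q / (2 * sigma^2) - lambda_pc * sigma + lcur)
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          sc <- sigma / sn
          u <- u * sc; v <- v * sc
          sigma <- sn
          if (it > spec$burnin) accept["centered"] <- accept["centered"] + 1
        }
      }

      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
        s <- (ch - 1) * n_keep + (it - spec$burnin) %/% spec$thin
        bdraw <- sigma * (sqrt(phi) * u + sqrt(1 - phi) * v)
        res$beta[s, ] <- beta
        res$sigma[s] <- sigma
        res$phi[s] <- phi
        res$u[s, ] <- u
        res$b[s, ] <- bdraw
        res$theta[s, ] <- as.numeric(X %*% beta) + bdraw
      }
    }
  }

  # convergence: split-chain Rhat on hyperparameters and fixed effects
  chain_of <- rep(seq_len(spec$chains), each = n_keep)
  mon <- cbind(res$beta, sigma = res$sigma, phi = res$phi)
  rhat <- apply(mon, 2, function(d) split_rhat(split(d, chain_of)))
  rhat <- rhat[!vapply(colnames(mon), function(nm)
    (nm == "sigma" && !is.null(spec$sigma_fixed)) ||
      (nm == "phi" && !is.null(spec$phi_fixed)), TRUE) | FALSE]
  bad <- rhat[!is.na(rhat) & rhat > spec$rhat_threshold]
  if (length(bad))
    warning("possible non-convergence (split-Rhat > ",
            spec$rhat_threshold, "): ",
            paste(sprintf("%s=%.3f", names(bad), bad), collapse = ", "))

  fit <- list(areas = ids, used = used, X = X, y = y_full, V = V_full,
              draws = c(res, list(p = expit(res$theta))),
              rhat = rhat,
              accept = ifelse(n_att > 0, accept / pmax(n_att, 1), NA),
              spec = spec)
  class(fit) <- "bym_fit"
  fit
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("bym_fit:", length(x$areas), "areas (", sum(x$used),
      "in likelihood ),", length(x$draws$sigma), "posterior draws\n")
  cat("  posterior mean sigma:", sprintf("%.3f", mean(x$draws$sigma)),
      " phi:", sprintf("%.3f", mean(x$draws$phi)), "\n")
  if (length(x$rhat))
    cat("  max split-Rhat:", sprintf("%.3f", max(x$rhat, na.rm = TRUE)), "\n")
  invisible(x)
}

# per-draw Gaussian log density of each likelihood observation
loglik_matrix <- function(fit) {
  obs <- which(fit$used)
  th <- fit$draws$theta[, obs, drop = FALSE]
  y <- fit$y[obs]; V <- fit$V[obs]
  ll <- -0.5 * (log(2 * pi * rep(V, each = nrow(th))) +
                  (rep(y, each = nrow(th)) - th)^2 /
                  rep(V, each = nrow(th)))
  dim(ll) <- dim(th)
  colnames(ll) <- fit$areas[obs]
  ll
}

#' Deviance information criterion of a fitted smoothing model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where the deviance is
#' `-2` times the Gaussian log likelihood of the logit-scale direct
#' estimates and `theta_bar` is the posterior mean linear predictor. Lower
#' is better; `pD` is the effective number of parameters.
#'
#' @param fit a `bym_fit`.
#' @return list with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`.
#' @export
compute_dic <- function(fit) {
  obs <- which(fit$used)
  y <- fit$y[obs]; V <- fit$V[obs]
  th <- fit$draws$theta[, obs, drop = FALSE]
  dev_draw <- rowSums(sweep((sweep(th, 2, y))^2, 2, V, "/")) +
    sum(log(2 * pi * V))
  th_bar <- colMeans(th)
  dev_at_mean <- sum((y - th_bar)^2 / V) + sum(log(2 * pi * V))
  dbar <- mean(dev_draw)
  list(dic = 2 * dbar - dev_at_mean, p_d = dbar - dev_at_mean,
       mean_deviance = dbar, deviance_at_mean = dev_at_mean)
}

#' Conditional predictive ordinates from a fitted smoothing model
#'
#' Leave-one-out predictive densities estimated by the harmonic-mean
#' (importance-sampling) identity `CPO_i = 1 / E_post[1 / f(y_i | theta_i)]`.
#' Low values flag areas whose direct estimate is unexpected under the model
#' fitted to the rest of the data. The effective sample size of the
#' importance weights is reported; estimates with ESS below `min_ess` are
#' flagged as unstable.
#'
#' @param fit a `bym_fit`.
#' @param min_ess stability threshold for the importance weights.
#' @return data frame: `area`, `cpo`, `ess`, `unstable`.
#' @export
compute_cpo <- function(fit, min_ess = 100) {
  ll <- loglik_matrix(fit)
  m <- apply(ll, 2, function(l) {
    w <- exp(-(l - max(l)))  # 1/f up to a constant
    c(cpo = exp(max(l)) / mean(w), ess = sum(w)^2 / sum(w^2))
  })
  data.frame(area = colnames(ll), cpo = m["cpo", ], ess = m["ess", ],
             unstable = m["ess", ] < min_ess,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior prevalence summaries per area
#'
#' @param fit a `bym_fit`.
#' @return data frame: `area`, `mean`, `q025`, `q975`, `insample` (TRUE if
#'   the area contributed to the likelihood).
#' @export
prevalence_summaries <- function(fit) {
  pd <- fit$draws$p
  data.frame(area = fit$areas,
             mean = colMeans(pd),
             q025 = apply(pd, 2, stats::quantile, 0.025, names = FALSE),
             q975 = apply(pd, 2, stats::quantile, 0.975, names = FALSE),
             insample = fit$used,
             row.names = NULL, stringsAsFactors = FALSE)
}
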