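# rebuild a phmm_params object from stored draw k
.params_from_draw <- function(fit, k) {
  spec <- fit$spec
  d <- fit$draws
  Q <- if (spec$perception_mode == "identity") NULL
  else if (spec$perception_mode == "shared")
    lapply(seq_len(spec$M), function(m)
      matrix(d$Q[k, m, 1L, , seq_len(spec$C_m[m])], spec$C, spec$C_m[m]))
  else lapply(seq_len(spec$M), function(m)
    lapply(seq_len(spec$S), function(s)
      matrix(d$Q[k, m, s, , seq_len(spec$C_m[m])], spec$C, spec$C_m[m])))
  grab <- function(a) lapply(seq_len(spec$M), function(m)
    matrix(a[k, m, seq_len(spec$J[m]), seq_len(spec$C_m[m])],
           spec$J[m], spec$C_m[m]))
  beta <- lapply(seq_len(spec$M), function(m)
    matrix(d$beta[k, m, seq_len(spec$J[m]), seq_len(max(spec$q, 1L))],
           spec$J[m], max(spec$q, 1L))[, seq_len(spec$q), drop = FALSE])
  phmm_params(spec, pi = matrix(d$pi[k, , ], spec$S, spec$C),
              P = lapply(seq_len(spec$S), function(s)
                matrix(d$P[k, s, , ], spec$C, spec$C)),
              Q = Q, tau = grab(d$tau), beta = beta, gamma = grab(d$gamma),
              Sigma = matrix(d$Sigma[k, , ], spec$r, spec$r))
}

#' Widely applicable information criterion
#'
#' `lppd = sum_points log mean_draws exp(ll)`, `p_waic = sum_points
#' var_draws(ll)`, `waic = -2 (lppd - p_waic)`. The default pointwise unit
#' is the cluster-visit, with the stored log-likelihood values conditional
#' on each draw's random effects (states marginalized through the forward
#' recursion). The `"marginal"` flavor instead Monte-Carlo-integrates the
#' random effects per cluster; its pointwise unit is the cluster.
#'
#' @param fit A `phmm_fit`.
#' @param flavor `"conditional"` (default) or `"marginal"`.
#' @param panel Required for the marginal flavor.
#' @param n_mc Monte Carlo draws for the marginal integral.
#' @param n_draws Number of posterior draws used by the marginal flavor.
#' @return List of class `phmm_waic` with `lppd`, `p_waic`, `waic`,
#'   `pointwise` (matrix draws x points) and `flavor`.
#' @export
waic <- function(fit, flavor = c("conditional", "marginal"), panel = NULL,
                 n_mc = 100L, n_draws = 100L) {
  flavor <- match.arg(flavor)
  if (flavor == "conditional") {
    K <- fit$n_draws
    if (K < 2L) stop("WAIC needs at least two draws")
    N <- fit$panel_info$N; n <- fit$panel_info$n
    keep <- rep(seq_len(n), each = N) <= rep(fit$panel_info$n_i, n)
    ll <- matrix(fit$draws$ll, K, N * n)[, keep, drop = FALSE]
  } else {
    if (is.null(panel)) stop("marginal WAIC needs the panel")
    ks <- unique(round(seq(1L, fit$n_draws, length.out = min(n_draws, fit$n_draws))))
    if (length(ks) < 2L) stop("WAIC needs at least two draws")
    ll <- t(vapply(ks, function(k)
      marginal_loglik(panel, .params_from_draw(fit, k), n_mc = n_mc),
      numeric(panel$N)))
  }
  lppd <- sum(apply(ll, 2L, .log_mean_exp))
  p_waic <- sum(apply(ll, 2L, stats::var))
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic), pointwise = ll,
                 flavor = flavor), class = "phmm_waic")
}

#' @export
print.phmm_waic <- function(x, ...) {
  cat(sprintf("WAIC (%s): %.1f  (lppd %.1f, p_waic %.1f)\n",
              x$flavor, x$waic, x$lppd, x$p_waic))
  invisible(x)
}

# simulate a replicate panel from one parameter draw, reusing the observed
# design (arms, covariates, follow-up lengths, missingness pattern)
.simulate_from_params <- function(params, panel) {
  spec <- params$spec
  N <- panel$N; n <- dim(panel$y)[2L]
  b <- .rmvnorm(N, sigma = params$Sigma)
  y <- array(NA_real_, dim(panel$y))
  for (i in seq_len(N)) {
    s <- panel$arm[i]; ni <- panel$n_i[i]
    Z <- simulate_family_chain(params$pi[s, ], params$P[[s]], ni)
    Qs <- lapply(seq_len(spec$M), function(m) .get_Q(params, m, s))
    Zm <- simulate_member_states(Z, Qs)
    Xi <- if (spec$q > 0) matrix(panel$X[i, seq_len(ni), ], ni, spec$q) else NULL
    y[i, seq_len(ni), , ] <- simulate_outcomes(matrix(Zm, ni, spec$M),
                                               b[i, ], Xi, params)
  }
  y[is.na(panel$y)] <- NA_real_
  y
}

#' Posterior predictive checks of outcome means and variances
#'
#' For each replicate a full panel is simulated from a sampled posterior
#' draw (new latent paths and random effects, observed design and
#' missingness retained) and the mean and variance of every outcome series
#' are recorded. Observed statistics are placed within the resulting
#' predictive distributions; placements outside `[0.01, 0.99]` are flagged.
#'
#' @param fit A `phmm_fit`.
#' @param panel The observed `phmm_panel`.
#' @param n_rep Number of predictive replicates.
#' @param seed RNG seed.
#' @return Data frame of class `phmm_ppc`: one row per statistic with the
#'   2.5/25/50/75/97.5% predictive quantiles, the observed value, its
#'   placement and an `extreme` flag.
#' @export
posterior_predictive_check <- function(fit, panel, n_rep = 1000L, seed = 1L) {
  set.seed(seed)
  spec <- fit$spec
  ks <- sample.int(fit$n_draws, n_rep, replace = TRUE)
  stat_names <- unlist(lapply(seq_len(spec$M), function(m)
    fit$panel_info$outcome_levels[[m]][seq_len(spec$J[m])]))
  nstat <- 2L * spec$r
  sims <- matrix(NA_real_, n_rep, nstat)
  for (rp in seq_len(n_rep)) {
    pk <- .params_from_draw(fit, ks[rp])
    yr <- .simulate_from_params(pk, panel)
    col <- 0L
    for (m in seq_len(spec$M)) for (j in seq_len(spec$J[m])) {
      col <- col + 1L
      v <- yr[, , m, j]
      sims[rp, col] <- mean(v, na.rm = TRUE)
      sims[rp, spec$r + col] <- stats::var(as.vector(v), na.rm = TRUE)
    }
  }
  obs <- numeric(nstat); col <- 0L
  for (m in seq_len(spec$M)) for (j in seq_len(spec$J[m])) {
    col <- col + 1L
    v <- panel$y[, , m, j]
    obs[col] <- mean(v, na.rm = TRUE)
    obs[spec$r + col] <- stats::var(as.vector(v), na.rm = TRUE)
  }
  qs <- t(apply(sims, 2L, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  placement <- vapply(seq_len(nstat), function(cc)
    mean(sims[, cc] <= obs[cc]), 0)
  out <- data.frame(
    statistic = c(paste0("mean_", stat_names), paste0("var_", stat_names)),
    q2.5 = qs[, 1L], q25 = qs[, 2L], q50 = qs[, 3L], q75 = qs[, 4L],
    q97.5 = qs[, 5L], observed = obs, placement = placement,
    extreme = placement < 0.01 | placement > 0.99)
  rownames(out) <- NULL
  class(out) <- c("phmm_ppc", "data.frame")
  out
}

#' Forecast pseudo-residuals
#'
#' One-step-ahead normal pseudo-residuals: for each outcome cell, the
#' predictive CDF of the observation given the cluster's data at earlier
#' visits is computed under each posterior draw (conditional on that
#' draw's random effects), averaged over draws, and mapped through the
#' standard normal quantile function. Visit-1 cells use the
#' initial-distribution predictive. Under a well-calibrated model the
#' residuals are approximately standard normal.
#'
#' @param fit A `phmm_fit` (random-effect draws stored).
#' @param panel The observed panel.
#' @param n_draws Number of posterior draws to average over.
#' @param eps CDF values are clipped to `(eps, 1 - eps)`; the number of
#'   clipped cells is recorded in the `"clipped"` attribute.
#' @return Array shaped like `panel$y` of pseudo-residuals (`NA` for
#'   missing cells).
#' @export
pseudo_residuals <- function(fit, panel, n_draws = 100L, eps = 1e-10) {
  spec <- fit$spec
  N <- panel$N; n <- dim(panel$y)[2L]; C <- spec$C
  ks <- unique(round(seq(1L, fit$n_draws, length.out = min(n_draws, fit$n_draws))))
  cdf_sum <- array(0, dim(panel$y))
  for (k in ks) {
    pk <- .params_from_draw(fit, k)
    bk <- matrix(fit$draws$b[k, , ], N, spec$r)
    lg <- .logG(panel, pk, b = bk, g_form = fit$config$g_form)
    fw <- .forward_all(lg, panel$arm, pk$pi, pk$P, panel$n_i)
    xb <- .xbeta_array(panel, pk)
    mom <- .emission_moments(pk)
    pred <- array(0, c(N, n, C))
    pred[, 1L, ] <- pk$pi[panel$arm, , drop = FALSE]
    if (n > 1L) for (t in 2:n) for (s in seq_len(spec$S)) {
      rows <- panel$arm == s
      if (any(rows))
        pred[rows, t, ] <- matrix(fw$alpha[, t - 1L, ], N, C)[rows, , drop = FALSE] %*% pk$P[[s]]
    }
    for (m in seq_len(spec$M)) {
      Cm <- spec$C_m[m]
      w <- array(0, c(N, n, Cm))
      for (s in seq_len(spec$S)) {
        rows <- panel$arm == s
        if (!any(rows)) next
        pm <- matrix(pred, N * n, C)
        w_s <- pm[rep(rows, n), , drop = FALSE] %*% .get_Q(pk, m, s)
        wm <- matrix(w, N * n, Cm)
        wm[rep(rows, n), ] <- w_s
        w <- array(wm, c(N, n, Cm))
      }
      for (j in seq_len(spec$J[m])) {
        e <- .global_index(spec$J, m, j)
        cc <- matrix(0, N, n)
        for (kk in seq_len(Cm))
          cc <- cc + w[, , kk] *
            stats::pnorm(panel$y[, , m, j],
                         mom[[m]]$means[j, kk] + xb[, , m, j] + bk[, e],
                         sqrt(mom[[m]]$vars[j, kk]))
        cdf_sum[, , m, j] <- cdf_sum[, , m, j] + cc
      }
    }
  }
  u <- cdf_sum / length(ks)
  clipped <- sum(u < eps | u > 1 - eps, na.rm = TRUE)
  u <- pmin(pmax(u, eps), 1 - eps)
  res <- stats::qnorm(u)
  res[is.na(panel$y)] <- NA_real_
  attr(res, "clipped") <- clipped
  attr(res, "eps") <- eps
  res
}

.ess <- function(x) {
  K <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(K - 1L, 500L), plot = FALSE)$acf[-1L]
  s <- 0; m <- 1L
  while (m + 1L <= length(rho)) {
    g <- rho[m] + rho[m + 1L]
    if (g < 0) break
    s <- s + g
    m <- m + 2L
  }
  max(1, K / (1 + 2 * s))
}

.split_rhat <- function(x) {
  K <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  z <- stats::qnorm((rank(x) - 0.375) / (K + 0.25))  # rank-normalized
  half <- floor(K / 2)
  chains <- list(z[seq_len(half)], z[(K - half + 1):K])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars); B <- half * stats::var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size and split-chain diagnostics
#'
#' Rank-based split-R-hat and autocorrelation-based effective sample size
#' for every scalar parameter in the stored draws. Parameters with
#' `rhat > threshold` or degenerate (constant) traces are flagged.
#'
#' @param fit A `phmm_fit`.
#' @param threshold R-hat warning threshold.
#' @return Data frame with columns `parameter`, `mean`, `ess`, `rhat`,
#'   `flag`.
#' @export
convergence_summary <- function(fit, threshold = 1.05) {
  spec <- fit$spec
  d <- fit$draws
  K <- fit$n_draws
  cols <- list()
  for (s in seq_len(spec$S)) for (cc in seq_len(spec$C))
    cols[[sprintf("pi[%d,%d]", s, cc)]] <- d$pi[, s, cc]
  for (s in seq_len(spec$S)) for (k in seq_len(spec$C)) for (j in seq_len(spec$C))
    cols[[sprintf("P[%d,%d->%d]", s, k, j)]] <- d$P[, s, k, j]
  nq <- dim(d$Q)[3L]
  if (spec$perception_mode != "identity")
    for (m in seq_len(spec$M)) for (s in seq_len(nq))
      for (k in seq_len(spec$C)) for (j in seq_len(spec$C_m[m]))
        cols[[sprintf("Q[m%d%s,%d->%d]", m,
                      if (nq > 1L) sprintf(",s%d", s) else "", k, j)]] <-
          d$Q[, m, s, k, j]
  for (m in seq_len(spec$M)) for (j in seq_len(spec$J[m]))
    for (k in seq_len(spec$C_m[m])) {
      cols[[sprintf("mean[m%d,o%d,state%d]", m, j, k)]] <-
        rowSums(matrix(d$tau[, m, j, seq_len(k)], K, k))
      cols[[sprintf("var[m%d,o%d,state%d]", m, j, k)]] <- d$sigma2[, m, j, k]
    }
  for (e in seq_len(spec$r))
    cols[[sprintf("Sigma[%d,%d]", e, e)]] <- d$Sigma[, e, e]
  out <- data.frame(
    parameter = names(cols),
    mean = vapply(cols, mean, 0),
    ess = vapply(cols, .ess, 0),
    rhat = vapply(cols, .split_rhat, 0))
  out$flag <- is.na(out$rhat) | out$rhat > threshold
  rownames(out) <- NULL
  out
}
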