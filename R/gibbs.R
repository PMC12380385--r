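#' Sampler configuration
#'
#' Two-phase MCMC schedule: a short adaptation run whose posterior means
#' seed a longer inference run. Defaults follow the 4000/3000 + 40000/30000
#' schedule; reduced schedules are appropriate for simulation studies.
#'
#' @param phase1_iter,phase1_burn Phase-1 iterations and burn-in.
#' @param phase2_iter,phase2_burn Phase-2 iterations and burn-in.
#' @param thin Thinning interval for stored phase-2 draws.
#' @param seed Integer RNG seed.
#' @param variance_param `"direct"` samples per-state variances from their
#'   conjugate inverse-Gamma full conditionals (default); `"increments"`
#'   runs random-walk Metropolis on the positive variance increments under
#'   the inverse-Gamma increments prior (enforcing nondecreasing state
#'   variances).
#' @param g_form Mixture-matrix form, see [member_mixture_vector()].
#' @param relabel Apply the per-draw relabeling rule (order states by
#'   decreasing reference-outcome state mean; align member states through
#'   the dominant diagonal of the perception matrix).
#' @param store_latent Store latent-path draws (needed for decoding).
#' @param prior A [prior_config()].
#' @param mh_sd Random-walk scale for the increments sampler.
#' @param ridge Relative ridge jitter used when a regression full
#'   conditional is rank deficient (e.g. a state never visited).
#' @return Object of class `phmm_sampler_config`.
#' @export
sampler_config <- function(phase1_iter = 4000L, phase1_burn = 3000L,
                           phase2_iter = 40000L, phase2_burn = 30000L,
                           thin = 10L, seed = 1L,
                           variance_param = c("direct", "increments"),
                           g_form = c("generative", "printed"),
                           relabel = TRUE, store_latent = TRUE,
                           prior = prior_config(), mh_sd = 0.3,
                           ridge = 1e-8) {
  variance_param <- match.arg(variance_param)
  g_form <- match.arg(g_form)
  if (phase1_burn >= phase1_iter || phase2_burn >= phase2_iter)
    stop("burn-in must be smaller than the iteration count")
  if (min(phase1_iter, phase2_iter, thin) < 1L) stop("counts must be positive")
  structure(list(phase1_iter = as.integer(phase1_iter),
                 phase1_burn = as.integer(phase1_burn),
                 phase2_iter = as.integer(phase2_iter),
                 phase2_burn = as.integer(phase2_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 variance_param = variance_param, g_form = g_form,
                 relabel = relabel, store_latent = store_latent,
                 prior = prior, mh_sd = mh_sd, ridge = ridge),
            class = "phmm_sampler_config")
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

.rdirichlet_rows <- function(alpha_mat) {
  x <- matrix(stats::rgamma(length(alpha_mat), shape = alpha_mat),
              nrow(alpha_mat), ncol(alpha_mat))
  x / rowSums(x)
}

# vectorized categorical sampler: one draw per row of (unnormalized,
# non-negative) probability matrix p, using uniforms u
.rcat <- function(p, u) {
  n <- nrow(p); C <- ncol(p)
  tot <- rowSums(p)
  if (any(tot <= 0 | !is.finite(tot)))
    stop("degenerate categorical probabilities at row ",
         which(tot <= 0 | !is.finite(tot))[1L])
  target <- u * tot
  cs <- p[, 1L]
  z <- rep(1L, n)
  if (C > 1L) for (k in 2:C) {
    z <- z + (target > cs)
    cs <- cs + p[, k]
  }
  z
}

#' Forward-filtering backward-sampling of one family state path
#'
#' Draws a cluster's family state sequence from its exact full conditional
#' given the visit-level mixture emissions: the final state is drawn
#' proportionally to the final forward probabilities and the backward pass
#' uses the transition matrix and the filtered probabilities.
#'
#' @param logG `n x C` matrix of log mixture-emission diagonals.
#' @param pi_row Initial probability vector.
#' @param P `C x C` transition matrix.
#' @return Integer state sequence of length `n`.
#' @export
ffbs_family_states <- function(logG, pi_row, P) {
  n <- nrow(logG); C <- ncol(logG)
  fw <- .forward_all(array(logG, c(1L, n, C)), arm = 1L,
                     pi = matrix(pi_row, 1L), P = list(P), n_i = n)
  drop(.ffbs_all(fw$alpha, arm = 1L, P = list(P), n_i = n))
}

# backward sampling for all clusters; alpha from .forward_all
.ffbs_all <- function(alpha, arm, P, n_i) {
  N <- dim(alpha)[1L]; n <- dim(alpha)[2L]; C <- dim(alpha)[3L]
  Z <- matrix(NA_integer_, N, n)
  u <- matrix(stats::runif(N * n), N, n)
  for (t in n:1) {
    at_end <- which(n_i == t)
    if (length(at_end))
      Z[cbind(at_end, t)] <- .rcat(matrix(alpha[, t, ], N, C)[at_end, , drop = FALSE],
                                   u[at_end, t])
    cont <- which(n_i > t)
    if (length(cont)) {
      w <- matrix(alpha[, t, ], N, C)[cont, , drop = FALSE]
      znext <- Z[cbind(cont, t + 1L)]
      fac <- matrix(0, length(cont), C)
      for (s in seq_along(P)) {
        rs <- arm[cont] == s
        if (any(rs)) fac[rs, ] <- t(P[[s]][, znext[rs], drop = FALSE])
      }
      Z[cbind(cont, t)] <- .rcat(w * fac, u[cont, t])
    }
  }
  Z
}

#' Sample member perceived states given the family path
#'
#' Each member-visit state is drawn from its full conditional,
#' `P(Zm = k) proportional to Q[Z, k] * prod_j f(y_j | k)`, independently
#' across members and visits given the family states.
#'
#' @param logf `n x C_m` matrix of summed log emission densities for the
#'   member (rows are visits).
#' @param Z Integer family state sequence of length `n`.
#' @param Q The member's `C x C_m` perception matrix.
#' @return Integer member state sequence.
#' @export
sample_member_states <- function(logf, Z, Q) {
  mx <- apply(logf, 1L, max)
  f <- exp(logf - mx)
  pr <- f * Q[Z, , drop = FALSE]
  .rcat(pr, stats::runif(length(Z)))
}

#' Conjugate update of initial and transition probabilities
#'
#' Each arm's initial-probability row is Dirichlet with the prior
#' concentration plus the arm's initial-state counts; each transition row is
#' Dirichlet with the prior plus the arm's transition counts. Empty counts
#' fall back to the prior.
#'
#' @param Z `N x n` matrix of family states (`NA` beyond a cluster's
#'   follow-up).
#' @param arm Integer arm per cluster.
#' @param S,C Arm and state counts.
#' @param conc Dirichlet prior concentration.
#' @param conditional If `TRUE`, return the full-conditional Dirichlet
#'   parameters instead of a draw.
#' @return List with `pi` (`S x C`) and `P` (list of `S` matrices), or the
#'   Dirichlet parameters when `conditional = TRUE`.
#' @export
update_chain_probs <- function(Z, arm, S, C, conc = 1, conditional = FALSE) {
  n <- ncol(Z)
  pi_alpha <- matrix(conc, S, C)
  P_alpha <- array(conc, c(S, C, C))
  for (s in seq_len(S)) {
    rows <- arm == s
    z1 <- Z[rows, 1L]
    pi_alpha[s, ] <- conc + tabulate(z1[!is.na(z1)], C)
    if (n > 1L) {
      from <- as.vector(Z[rows, -n, drop = FALSE])
      to <- as.vector(Z[rows, -1L, drop = FALSE])
      ok <- !is.na(from) & !is.na(to)
      if (any(ok)) {
        tc <- tabulate((to[ok] - 1L) * C + from[ok], C * C)
        P_alpha[s, , ] <- conc + matrix(tc, C, C)
      }
    }
  }
  if (conditional) return(list(pi_alpha = pi_alpha, P_alpha = P_alpha))
  list(pi = .rdirichlet_rows(pi_alpha),
       P = lapply(seq_len(S), function(s) .rdirichlet_rows(P_alpha[s, , ])))
}

#' Conjugate update of perception matrices
#'
#' Row `(m, k)` (and arm `s` in arm-specific mode) is Dirichlet with prior
#' concentration plus the count of visits where the family is in state `k`
#' and member `m` perceives state `j`. Shared mode pools arms; identity
#' mode returns identity matrices without sampling.
#'
#' @param Z `N x n` family states.
#' @param Zm List of `M` matrices `N x n` of member states.
#' @param arm Integer arm per cluster.
#' @param spec A `phmm_spec`.
#' @param conc Dirichlet prior concentration.
#' @param conditional If `TRUE`, return Dirichlet parameters.
#' @return `Q` in the layout of [phmm_params()] (or parameter counts).
#' @export
update_perception <- function(Z, Zm, arm, spec, conc = 1, conditional = FALSE) {
  C <- spec$C
  if (spec$perception_mode == "identity") {
    if (conditional) stop("identity mode has no perception full conditional")
    return(lapply(seq_len(spec$M), function(m) diag(C)))
  }
  counts <- function(rows, m) {
    Cm <- spec$C_m[m]
    zf <- as.vector(Z[rows, , drop = FALSE])
    zm <- as.vector(Zm[[m]][rows, , drop = FALSE])
    ok <- !is.na(zf) & !is.na(zm)
    matrix(tabulate((zm[ok] - 1L) * C + zf[ok], C * Cm), C, Cm)
  }
  if (spec$perception_mode == "shared") {
    alpha <- lapply(seq_len(spec$M), function(m)
      conc + counts(rep(TRUE, nrow(Z)), m))
    if (conditional) return(alpha)
    lapply(alpha, .rdirichlet_rows)
  } else {
    alpha <- lapply(seq_len(spec$M), function(m)
      lapply(seq_len(spec$S), function(s) conc + counts(arm == s, m)))
    if (conditional) return(alpha)
    lapply(alpha, function(am) lapply(am, .rdirichlet_rows))
  }
}

#' Joint draw of mean increments and covariate coefficients
#'
#' The regression block for one member-outcome series has a flat prior, so
#' its full conditional is the weighted-least-squares Gaussian with weights
#' equal to inverse state variances. The design couples the cumulative
#' state encoding (column `l` indicates state `>= l`, so coefficients are
#' the mean increments directly) with the covariates.
#'
#' @param y Observed cells (response minus the random-effect contribution).
#' @param states Member state per cell.
#' @param sigma2 Per-state variance vector (length `C_m`).
#' @param X Optional covariate matrix (cells x q).
#' @param conditional If `TRUE`, return the full-conditional mean and
#'   covariance.
#' @param ridge Relative jitter added to a rank-deficient normal matrix.
#' @return List with `tau` (increments), `beta`, and `jitter` (the ridge
#'   actually applied, 0 when none).
#' @export
update_regression <- function(y, states, sigma2, X = NULL,
                              conditional = FALSE, ridge = 1e-8) {
  C <- length(sigma2)
  W <- outer(states, seq_len(C), ">=") * 1
  if (!is.null(X)) W <- cbind(W, X)
  w <- 1 / sigma2[states]
  A <- crossprod(W, W * w)
  rhs <- crossprod(W, y * w)
  jit <- 0
  U <- tryCatch(chol(A), error = function(e) NULL)
  while (is.null(U)) {
    jit <- if (jit == 0) ridge * mean(diag(A)) else jit * 10
    U <- tryCatch(chol(A + jit * diag(ncol(A))), error = function(e) NULL)
    if (jit > 1e6 * mean(diag(A))) stop("regression normal matrix is singular")
  }
  mu <- backsolve(U, forwardsolve(t(U), rhs))
  if (conditional) return(list(mean = drop(mu), cov = chol2inv(U), jitter = jit))
  coef <- drop(mu + backsolve(U, stats::rnorm(ncol(W))))
  list(tau = coef[seq_len(C)],
       beta = if (is.null(X)) numeric(0) else coef[-seq_len(C)],
       jitter = jit)
}

.dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

#' Update state variances for one member-outcome series
#'
#' Direct mode (conjugate): each per-state variance is inverse-Gamma with
#' shape `a + n_k/2` and scale `b + SS_k/2`, drawn independently and then
#' converted to increments (which may be negative). Increments mode:
#' random-walk Metropolis on each positive increment under the
#' inverse-Gamma prior, preserving nondecreasing state variances.
#'
#' @param resid Residual cells (response minus full mean).
#' @param states Member state per cell.
#' @param C Number of member states.
#' @param a,b Inverse-Gamma prior shape and scale.
#' @param method `"direct"` or `"increments"`.
#' @param gamma_current Current increments (required for increments mode).
#' @param mh_sd Random-walk standard deviation on the log scale.
#' @param conditional If `TRUE` (direct mode), return the inverse-Gamma
#'   shapes and scales.
#' @return List with `sigma2` (per-state variances), `gamma` (increments)
#'   and `rejects` (increments mode Metropolis rejections).
#' @export
update_variances <- function(resid, states, C, a = 0.001, b = 0.0002,
                             method = c("direct", "increments"),
                             gamma_current = NULL, mh_sd = 0.3,
                             conditional = FALSE) {
  method <- match.arg(method)
  n_k <- tabulate(states, C)
  ss_k <- vapply(seq_len(C), function(k) sum(resid[states == k]^2), 0)
  if (method == "direct") {
    shape <- a + n_k / 2
    scale <- b + ss_k / 2
    if (conditional) return(list(shape = shape, scale = scale))
    sigma2 <- 1 / stats::rgamma(C, shape = shape, rate = scale)
    # numerical guard for states with no assigned cells (prior draws from
    # IG(0.001, .) can under/overflow)
    sigma2 <- pmin(pmax(sigma2, 1e-12), 1e12)
    return(list(sigma2 = sigma2, gamma = diff(c(0, sigma2)), rejects = 0L))
  }
  if (is.null(gamma_current)) stop("increments mode needs gamma_current")
  if (any(gamma_current <= 0))
    stop("increments mode requires strictly positive increments")
  gam <- gamma_current
  rejects <- 0L
  loglik_part <- function(v) {
    # only cells whose state variance involves the changed increment matter,
    # but recomputing all is cheap and simpler
    sum(stats::dnorm(resid, 0, sqrt(v[states]), log = TRUE))
  }
  for (l in seq_len(C)) {
    prop <- gam
    prop[l] <- gam[l] * exp(stats::rnorm(1L, 0, mh_sd))
    v_cur <- cumsum(gam); v_prop <- cumsum(prop)
    log_acc <- loglik_part(v_prop) - loglik_part(v_cur) +
      .dinvgamma_log(prop[l], a, b) - .dinvgamma_log(gam[l], a, b) +
      log(prop[l]) - log(gam[l])  # log-scale proposal Jacobian
    if (log(stats::runif(1L)) < log_acc) gam <- prop else rejects <- rejects + 1L
  }
  list(sigma2 = cumsum(gam), gamma = gam, rejects = rejects)
}

#' Draw one cluster's random-effect vector
#'
#' Combines the `N(0, Sigma)` prior with the Gaussian cell likelihoods.
#' Because each outcome series loads exactly one entry of `b`, the data
#' contribution is diagonal: `d[e]` is the summed precision of series `e`'s
#' cells and `h[e]` the precision-weighted residual sum (residuals exclude
#' the random effect). With no observations the prior is returned.
#'
#' @param d Data precision vector (length `r`).
#' @param h Precision-weighted residual sums (length `r`).
#' @param Sigma Random-effect covariance.
#' @param conditional If `TRUE` return the conditional mean and covariance.
#' @return Draw of length `r` (or the conditional moments).
#' @export
update_random_effects <- function(d, h, Sigma, conditional = FALSE) {
  Sinv <- chol2inv(chol(Sigma))
  A <- Sinv + diag(d, length(d))
  U <- chol(A)
  mu <- backsolve(U, forwardsolve(t(U), h))
  if (conditional) return(list(mean = drop(mu), cov = chol2inv(U)))
  drop(mu + backsolve(U, stats::rnorm(length(d))))
}

#' Conjugate update of the random-effect covariance
#'
#' `Sigma ~ IW(df + N, scale + sum_i b_i b_i')`.
#'
#' @param b `N x r` matrix of current random effects.
#' @param df Prior inverse-Wishart degrees of freedom.
#' @param scale Prior scale matrix.
#' @param conditional If `TRUE` return the posterior df and scale.
#' @return An `r x r` covariance draw.
#' @export
update_sigma <- function(b, df, scale, conditional = FALSE) {
  df_post <- df + nrow(b)
  scale_post <- scale + crossprod(b)
  if (conditional) return(list(df = df_post, scale = scale_post))
  W <- stats::rWishart(1L, df_post, chol2inv(chol(scale_post)))[, , 1L]
  chol2inv(chol(W))
}
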