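#' Gaussian emission log-density under the cumulative-sum parameterization
#'
#' Log density of an outcome cell given the member's latent state: mean
#' `cumsum(tau)[k] + x'beta + b`, variance `cumsum(gamma)[k]`. Missing cells
#' (`NA`) contribute `log 1 = 0` (the skip contract for missing data).
#'
#' @param y Outcome value(s); `NA` allowed.
#' @param state Latent state index (vectorized with `y`).
#' @param tau Mean increment vector for this outcome series.
#' @param gamma Variance increment vector; cumulative sums must be positive
#'   at the evaluated states.
#' @param x Optional covariate vector (or matrix, rows matching `y`).
#' @param beta Optional coefficient vector.
#' @param b Random-effect contribution (scalar or vector).
#' @return Log density value(s).
#' @export
emission_logpdf <- function(y, state, tau, gamma, x = NULL, beta = NULL, b = 0) {
  mu <- cumsum(tau)[state]
  v <- cumsum(gamma)[state]
  if (any(v <= 0)) stop("non-positive state variance at evaluated state")
  if (!is.null(x) && !is.null(beta)) {
    xb <- if (is.matrix(x)) drop(x %*% beta) else sum(x * beta)
    mu <- mu + xb
  }
  mu <- mu + b
  out <- stats::dnorm(y, mu, sqrt(v), log = TRUE)
  out[is.na(y)] <- 0
  out
}

#' Perception-marginalized emission vector for one member-visit
#'
#' Entry `h` is the probability of the member's observed outcome vector
#' given family state `h`, marginalized over the member's perceived state:
#' `sum_k Q[h, k] * prod_j f(y_j | k)` — the sum over the shared member
#' state lies outside the product over that member's outcomes, matching the
#' generative model in which one perceived state drives all of the member's
#' outcomes at a visit. `g_form = "printed"` instead computes
#' `prod_j sum_k f(y_j | k) Q[h, k]` (an outcome-wise mixture), provided
#' for comparison. The diagonal of the visit-level mixture matrix `G` is
#' the elementwise product of these vectors across members. A fully missing
#' member-visit returns a vector of ones.
#'
#' @param y Outcome vector of length `J_m` for the member at one visit.
#' @param Q The member's `C x C_m` perception matrix.
#' @param tau,gamma `J_m x C_m` increment matrices for the member.
#' @param x,beta Optional covariates (length `q`) and `J_m x q` coefficients.
#' @param b Random-effect entries for the member's outcomes (length `J_m`).
#' @param g_form `"generative"` (default) or `"printed"`.
#' @return Numeric vector of length `C` (rows of `Q`).
#' @export
member_mixture_vector <- function(y, Q, tau, gamma, x = NULL, beta = NULL,
                                  b = rep(0, length(y)),
                                  g_form = c("generative", "printed")) {
  g_form <- match.arg(g_form)
  tau <- as.matrix(tau); gamma <- as.matrix(gamma)
  Jm <- length(y); Cm <- ncol(Q)
  logf <- matrix(0, Jm, Cm)
  for (j in seq_len(Jm)) {
    bx <- if (!is.null(x) && !is.null(beta)) sum(x * beta[j, ]) else 0
    logf[j, ] <- emission_logpdf(rep(y[j], Cm), seq_len(Cm), tau[j, ],
                                 gamma[j, ], b = b[j] + bx)
  }
  if (g_form == "generative") {
    drop(Q %*% exp(colSums(logf)))
  } else {
    apply(exp(logf) %*% t(Q), 2L, prod)
  }
}

# per-member emission moments: list(means = J_m x C_m, vars = J_m x C_m)
.emission_moments <- function(params) {
  spec <- params$spec
  lapply(seq_len(spec$M), function(m) {
    list(means = .row_cumsum(params$tau[[m]]),
         vars = .row_cumsum(params$gamma[[m]]))
  })
}

# covariate contribution array [N, n, M, maxJ]
.xbeta_array <- function(panel, params) {
  spec <- params$spec
  out <- array(0, dim(panel$y))
  if (spec$q > 0) {
    Xf <- matrix(panel$X, ncol = spec$q)  # (N*n) x q
    for (m in seq_len(spec$M)) for (j in seq_len(spec$J[m]))
      out[, , m, j] <- Xf %*% params$beta[[m]][j, ]
  }
  out
}

# summed log emission densities per member: list of [N, n, C_m];
# NA cells contribute 0. b is N x r (or NULL for zeros).
.logf_members <- function(panel, params, b = NULL, xb = NULL) {
  spec <- params$spec
  N <- panel$N; n <- dim(panel$y)[2L]
  if (is.null(b)) b <- matrix(0, N, spec$r)
  if (is.null(xb)) xb <- .xbeta_array(panel, params)
  mom <- .emission_moments(params)
  lapply(seq_len(spec$M), function(m) {
    lf <- array(0, c(N, n, spec$C_m[m]))
    for (j in seq_len(spec$J[m])) {
      e <- .global_index(spec$J, m, j)
      resid0 <- panel$y[, , m, j] - xb[, , m, j] - b[, e]
      for (k in seq_len(spec$C_m[m])) {
        d <- stats::dnorm(resid0, mom[[m]]$means[j, k],
                          sqrt(mom[[m]]$vars[j, k]), log = TRUE)
        d[is.na(d)] <- 0
        lf[, , k] <- lf[, , k] + d
      }
    }
    lf
  })
}

# log diagonal of the visit mixture matrices G: [N, n, C]
.logG <- function(panel, params, b = NULL, g_form = "generative") {
  spec <- params$spec
  N <- panel$N; n <- dim(panel$y)[2L]; C <- spec$C
  out <- array(0, c(N, n, C))
  if (g_form == "generative") {
    lfs <- .logf_members(panel, params, b)
    out <- .logG_from_lfs(lfs, params, panel, n)
  } else {
    # printed form: product over outcomes of outcome-wise mixtures
    if (is.null(b)) b <- matrix(0, N, spec$r)
    xb <- .xbeta_array(panel, params)
    mom <- .emission_moments(params)
    for (m in seq_len(spec$M)) for (j in seq_len(spec$J[m])) {
      e <- .global_index(spec$J, m, j)
      resid0 <- panel$y[, , m, j] - xb[, , m, j] - b[, e]
      lf <- array(0, c(N, n, spec$C_m[m]))
      for (k in seq_len(spec$C_m[m]))
        lf[, , k] <- stats::dnorm(resid0, mom[[m]]$means[j, k],
                                  sqrt(mom[[m]]$vars[j, k]), log = TRUE)
      mx <- apply(lf, c(1L, 2L), max)
      f <- exp(lf - array(mx, dim(lf)))
      fm <- matrix(f, N * n, spec$C_m[m])
      miss <- is.na(panel$y[, , m, j])
      for (s in seq_len(spec$S)) {
        rows <- which(rep(panel$arm == s, n))
        if (!length(rows)) next
        v <- fm[rows, , drop = FALSE] %*% t(.get_Q(params, m, s))
        lv <- log(v) + mx[rep(panel$arm == s, n)]
        lv[miss[rep(panel$arm == s, n)], ] <- 0  # missing cell: no factor
        idx <- arrayInd(rows, c(N, n))
        for (h in seq_len(C))
          out[cbind(idx, h)] <- out[cbind(idx, h)] + lv[, h]
      }
    }
  }
  out
}

# scaled forward recursion over all clusters.
# logG: [N, n, C]; returns alpha [N, n, C] (rows normalized), logc [N, n]
# (0 beyond n_i), loglik [N].
.forward_all <- function(logG, arm, pi, P, n_i) {
  N <- dim(logG)[1L]; n <- dim(logG)[2L]; C <- dim(logG)[3L]
  S <- nrow(pi)
  alpha <- array(0, c(N, n, C))
  logc <- matrix(0, N, n)
  lgm <- matrix(logG, N * n, C)
  mxv <- lgm[, 1L]
  if (C > 1L) for (k in 2:C) mxv <- pmax(mxv, lgm[, k])
  mx <- matrix(mxv, N, n)
  G <- array(exp(lgm - mxv), c(N, n, C))
  pred <- pi[arm, , drop = FALSE]
  for (t in seq_len(n)) {
    if (t > 1L) {
      pred <- matrix(0, N, C)
      for (s in seq_len(S)) {
        rows <- arm == s
        if (any(rows))
          pred[rows, ] <- matrix(alpha[, t - 1L, ], N, C)[rows, , drop = FALSE] %*% P[[s]]
      }
    }
    a <- pred * matrix(G[, t, ], N, C)
    ssum <- rowSums(a)
    act <- n_i >= t
    if (any(ssum[act] <= 0 | !is.finite(ssum[act]))) {
      bad <- which(act & (ssum <= 0 | !is.finite(ssum)))[1L]
      stop(sprintf("zero/non-finite total likelihood at cluster %d, visit %d", bad, t))
    }
    alpha[, t, ] <- a / ifelse(ssum > 0, ssum, 1)
    logc[, t] <- ifelse(act, log(ssum) + mx[, t], 0)
    if (any(!act) && t > 1L)  # freeze finished clusters
      alpha[!act, t, ] <- alpha[!act, t - 1L, ]
  }
  list(alpha = alpha, logc = logc, loglik = rowSums(logc))
}

#' Forward recursion for one cluster
#'
#' Computes scaled forward probabilities and the conditional log-likelihood
#' of one cluster's outcome sequence given the random effects, with
#' per-visit scaling constants for numerical stability.
#'
#' @param panel A `phmm_panel`.
#' @param params A `phmm_params`.
#' @param i Cluster index.
#' @param b Random-effect vector for the cluster (default zeros).
#' @param g_form Mixture form, see [member_mixture_vector()].
#' @return List with `alpha` (`n_i x C`, rows summing to 1), `log_scale`
#'   (per-visit log normalizing constants) and `loglik`.
#' @export
forward_filter <- function(panel, params, i, b = NULL,
                           g_form = c("generative", "printed")) {
  g_form <- match.arg(g_form)
  spec <- params$spec
  if (is.null(b)) b <- rep(0, spec$r)
  p1 <- .panel_single(panel, i)
  lg <- .logG(p1, params, b = matrix(b, 1L), g_form = g_form)
  fw <- tryCatch(.forward_all(lg, p1$arm, params$pi, params$P, p1$n_i),
                 error = function(e) e)
  if (inherits(fw, "error"))
    return(list(alpha = NULL, log_scale = NULL, loglik = -Inf,
                diagnostic = conditionMessage(fw)))
  n_i <- p1$n_i[1L]
  list(alpha = matrix(fw$alpha[1L, seq_len(n_i), ], n_i, spec$C),
       log_scale = fw$logc[1L, seq_len(n_i)], loglik = fw$loglik[1L])
}

# one-cluster view of a panel
.panel_single <- function(panel, i) {
  p <- panel
  p$y <- panel$y[i, , , , drop = FALSE]
  p$X <- panel$X[i, , , drop = FALSE]
  p$arm <- panel$arm[i]; p$n_i <- panel$n_i[i]; p$N <- 1L
  p$cluster_ids <- panel$cluster_ids[i]
  p
}

#' Per-cluster conditional log-likelihood
#'
#' Log-likelihood of each cluster's data given fixed random effects `b`
#' (states marginalized by the forward recursion).
#'
#' @param panel A `phmm_panel`.
#' @param params A `phmm_params`.
#' @param b `N x r` matrix of random effects (default zeros).
#' @param g_form Mixture form.
#' @return Numeric vector of length `N`.
#' @export
loglik_conditional <- function(panel, params, b = NULL,
                               g_form = c("generative", "printed")) {
  g_form <- match.arg(g_form)
  lg <- .logG(panel, params, b = b, g_form = g_form)
  .forward_all(lg, panel$arm, params$pi, params$P, panel$n_i)$loglik
}

#' Marginal log-likelihood over random effects
#'
#' Per-cluster log-likelihood either conditional on supplied random effects
#' or integrated over `b ~ N(0, Sigma)` by Monte Carlo.
#'
#' @param panel A `phmm_panel`.
#' @param params A `phmm_params`.
#' @param b Optional `N x r` matrix: if given, the conditional values are
#'   returned.
#' @param n_mc Number of Monte Carlo draws for the integral.
#' @param g_form Mixture form.
#' @return Numeric vector of per-cluster log-likelihood values.
#' @export
marginal_loglik <- function(panel, params, b = NULL, n_mc = 1000L,
                            g_form = c("generative", "printed")) {
  g_form <- match.arg(g_form)
  if (!is.null(b)) return(loglik_conditional(panel, params, b, g_form))
  ev <- eigen(params$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite")
  ll <- matrix(0, n_mc, panel$N)
  for (d in seq_len(n_mc)) {
    bd <- .rmvnorm(panel$N, sigma = params$Sigma)
    ll[d, ] <- loglik_conditional(panel, params, bd, g_form)
  }
  apply(ll, 2L, .log_mean_exp)
}

.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
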