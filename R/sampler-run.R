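# relabeling: order states of a reference member-outcome series by
# decreasing state mean, align family states to the reference member via
# the dominant diagonal of its perception matrix, then align the remaining
# members the same way. Returns permutations (new index -> old index).
.perms <- function(C) {
  if (C == 1L) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) { out[[length(out) + 1L]] <<- prefix; return() }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(C))
  out
}

.relabel_perms <- function(params, spec, ref_member, ref_outcome) {
  mode <- spec$perception_mode
  mean_ord <- function(m) {
    mu <- cumsum(params$tau[[m]][ref_outcome, ])
    order(mu, decreasing = TRUE)
  }
  if (mode == "identity") {
    sig <- mean_ord(ref_member)
    return(list(family = sig, members = rep(list(sig), spec$M)))
  }
  avg_Q <- function(m) {
    if (mode == "arm_specific") Reduce(`+`, params$Q[[m]]) / spec$S
    else params$Q[[m]]
  }
  sig_ref <- mean_ord(ref_member)
  Qr <- avg_Q(ref_member)
  cands <- .perms(spec$C)
  scores <- vapply(cands, function(p) sum(diag(Qr[p, sig_ref, drop = FALSE])), 0)
  sig_f <- cands[[which.max(scores)]]
  members <- vector("list", spec$M)
  members[[ref_member]] <- sig_ref
  for (m in seq_len(spec$M)) {
    if (m == ref_member) next
    Qm <- avg_Q(m)
    cm <- .perms(spec$C_m[m])
    sc <- vapply(cm, function(p) {
      d <- min(spec$C, spec$C_m[m])
      sum(Qm[sig_f, p, drop = FALSE][cbind(seq_len(d), seq_len(d))])
    }, 0)
    members[[m]] <- cm[[which.max(sc)]]
  }
  list(family = sig_f, members = members)
}

# apply label permutations to the whole sampler state; inv[sig[j]] = j
.apply_relabel <- function(st, spec, perms) {
  sig_f <- perms$family
  if (all(sig_f == seq_len(spec$C)) &&
      all(vapply(seq_len(spec$M), function(m)
        all(perms$members[[m]] == seq_len(spec$C_m[m])), TRUE)))
    return(NULL)
  inv_f <- integer(spec$C); inv_f[sig_f] <- seq_len(spec$C)
  st$params$pi <- st$params$pi[, sig_f, drop = FALSE]
  st$params$P <- lapply(st$params$P, function(p) p[sig_f, sig_f, drop = FALSE])
  for (m in seq_len(spec$M)) {
    sig_m <- perms$members[[m]]
    inv_m <- integer(spec$C_m[m]); inv_m[sig_m] <- seq_len(spec$C_m[m])
    if (spec$perception_mode == "arm_specific") {
      st$params$Q[[m]] <- lapply(st$params$Q[[m]],
                                 function(q) q[sig_f, sig_m, drop = FALSE])
    } else if (spec$perception_mode == "shared") {
      st$params$Q[[m]] <- st$params$Q[[m]][sig_f, sig_m, drop = FALSE]
    }
    for (j in seq_len(spec$J[m])) {
      mu <- cumsum(st$params$tau[[m]][j, ])[sig_m]
      v <- cumsum(st$params$gamma[[m]][j, ])[sig_m]
      st$params$tau[[m]][j, ] <- diff(c(0, mu))
      st$params$gamma[[m]][j, ] <- diff(c(0, v))
    }
    st$Zm[[m]][] <- inv_m[st$Zm[[m]]]
  }
  st$Z[] <- inv_f[st$Z]
  st
}

# crude initialization: per-visit quantile binning of a composite
# standardized outcome score (high score -> state 1)
.init_states <- function(panel, C) {
  N <- panel$N; n <- dim(panel$y)[2L]
  comp <- matrix(0, N, n); cnt <- matrix(0, N, n)
  for (m in seq_len(panel$M)) for (j in seq_len(panel$J[m])) {
    v <- panel$y[, , m, j]
    mu <- mean(v, na.rm = TRUE); sd <- stats::sd(as.vector(v), na.rm = TRUE)
    z <- (v - mu) / max(sd, 1e-12)
    ok <- !is.na(z)
    comp[ok] <- comp[ok] + z[ok]; cnt[ok] <- cnt[ok] + 1
  }
  score <- ifelse(cnt > 0, comp / cnt, 0)
  qs <- stats::quantile(score[cnt > 0], probs = seq_len(C - 1) / C, names = FALSE)
  Z <- matrix(1L + rowSums(outer(as.vector(-score), -qs, ">")), N, n)
  Z[col(Z) > panel$n_i] <- NA_integer_
  Z
}

.check_panel_spec <- function(panel, spec) {
  if (panel$M != spec$M || !all(panel$J == spec$J))
    stop("panel member/outcome layout does not match spec")
  if (max(panel$arm) > spec$S) stop("panel has more arms than spec$S")
  if (panel$q != spec$q)
    stop(sprintf("panel has %d covariates but spec$q = %d", panel$q, spec$q))
  invisible(TRUE)
}

#' Run the two-phase Gibbs sampler
#'
#' Alternates forward-filtering backward-sampling of family states, member
#' state draws, and conjugate updates of all parameter blocks (Dirichlet
#' rows, weighted-least-squares regression, inverse-Gamma variances,
#' Gaussian random effects, inverse-Wishart covariance). Phase 1 is a short
#' adaptation run; phase 2 restarts from the phase-1 posterior means and
#' its post-burn-in draws are stored (thinned), together with per
#' cluster-visit pointwise log-likelihood values (conditional on the
#' draw's random effects, states marginalized) for WAIC.
#'
#' @param panel A `phmm_panel`.
#' @param spec A `phmm_spec`.
#' @param config A [sampler_config()].
#' @param fixed_emission Optional list with elements `tau`, `beta`, `gamma`
#'   (in [phmm_params()] layout) freezing the emission block at the given
#'   values: the regression and variance updates are skipped and per-draw
#'   relabeling is disabled (labels are pinned by the fixed emissions).
#'   Used by the constrained perception approximation.
#' @return Object of class `phmm_fit` holding draw arrays (`pi`, `P`, `Q`,
#'   `tau`, `gamma`, `sigma2`, `beta`, `Sigma`, `b`, optional `Z`/`Zm`),
#'   pointwise log-likelihoods `ll`, and run metadata.
#' @export
run_sampler <- function(panel, spec, config = sampler_config(),
                        fixed_emission = NULL) {
  .check_panel_spec(panel, spec)
  prior <- .resolve_prior(config$prior, spec)
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]

  N <- panel$N; n <- dim(panel$y)[2L]; C <- spec$C; M <- spec$M
  r <- spec$r; q <- spec$q; S <- spec$S
  Jmax <- max(spec$J); Cmax <- max(spec$C_m)
  vmask_flat <- rep(seq_len(n), each = N) <= rep(panel$n_i, n)  # cells valid

  # per-series flattened observation structures
  series <- list()
  Xflat <- if (q > 0) matrix(panel$X, ncol = q) else NULL
  for (m in seq_len(M)) for (j in seq_len(spec$J[m])) {
    yf <- as.vector(panel$y[, , m, j])
    idx <- which(!is.na(yf) & vmask_flat)
    series[[length(series) + 1L]] <- list(
      m = m, j = j, e = .global_index(spec$J, m, j),
      idx = idx, y = yf[idx], i = ((idx - 1L) %% N) + 1L,
      X = if (q > 0) Xflat[idx, , drop = FALSE] else NULL)
  }

  # --- initialization ---
  Z <- .init_states(panel, C)
  Zm <- lapply(seq_len(M), function(m) {
    zm <- Z; zm[!is.na(zm)] <- pmin(zm[!is.na(zm)], spec$C_m[m]); zm
  })
  b <- matrix(0, N, r)
  Sigma <- prior$iw_scale
  cp <- update_chain_probs(Z, panel$arm, S, C, prior$dirichlet_conc,
                           conditional = TRUE)
  pi0 <- cp$pi_alpha / rowSums(cp$pi_alpha)
  P0 <- lapply(seq_len(S), function(s)
    cp$P_alpha[s, , ] / rowSums(cp$P_alpha[s, , ]))
  Qc <- update_perception(Z, Zm, panel$arm, spec, prior$dirichlet_conc,
                          conditional = spec$perception_mode != "identity")
  Q0 <- if (spec$perception_mode == "identity") Qc
    else if (spec$perception_mode == "shared") lapply(Qc, function(a) a / rowSums(a))
    else lapply(Qc, function(am) lapply(am, function(a) a / rowSums(a)))
  tau0 <- lapply(seq_len(M), function(m) matrix(0, spec$J[m], spec$C_m[m]))
  gamma0 <- tau0
  beta0 <- lapply(seq_len(M), function(m) matrix(0, spec$J[m], q))
  sig2 <- lapply(seq_len(M), function(m) matrix(1, spec$J[m], spec$C_m[m]))
  for (sr in series) {
    st0 <- as.vector(Zm[[sr$m]])[sr$idx]
    Cm <- spec$C_m[sr$m]
    reg <- update_regression(sr$y, st0, rep(stats::var(sr$y), Cm), sr$X,
                             conditional = TRUE, ridge = config$ridge)
    cf <- reg$mean
    tau0[[sr$m]][sr$j, ] <- cf[seq_len(Cm)]
    if (q > 0) beta0[[sr$m]][sr$j, ] <- cf[-seq_len(Cm)]
    W <- cbind(outer(st0, seq_len(Cm), ">=") * 1, sr$X)
    rs <- sr$y - drop(W %*% cf)
    v0 <- max(stats::var(rs), 1e-8)
    # mildly increasing initial state variances keep the increments-mode
    # prior support satisfied; direct mode is indifferent
    g0 <- c(v0, rep(v0 * 0.01, Cm - 1L))
    sig2[[sr$m]][sr$j, ] <- cumsum(g0)
    gamma0[[sr$m]][sr$j, ] <- g0
  }
  if (!is.null(fixed_emission)) {
    tau0 <- lapply(fixed_emission$tau, as.matrix)
    gamma0 <- lapply(fixed_emission$gamma, as.matrix)
    if (!is.null(fixed_emission$beta))
      beta0 <- lapply(fixed_emission$beta, as.matrix)
    sig2 <- lapply(gamma0, .row_cumsum)
    config$relabel <- FALSE
  }
  params <- phmm_params(spec, pi = pi0, P = P0,
                        Q = if (spec$perception_mode == "identity") NULL else Q0,
                        tau = tau0, beta = beta0, gamma = gamma0, Sigma = Sigma)

  st <- list(params = params, b = b, Z = Z, Zm = Zm, sig2 = sig2)
  relabel_count <- 0L; relabel_skipped <- 0L
  mh_rejects <- 0L; jitter_events <- 0L
  Sinv_prior_scale <- prior$iw_scale

  one_iter <- function(st, want_ll = FALSE) {
    params <- st$params
    xb <- .xbeta_array(panel, params)
    lfs <- .logf_members(panel, params, st$b, xb)
    logG <- .logG_from_lfs(lfs, params, panel, n)
    fw <- .forward_all(logG, panel$arm, params$pi, params$P, panel$n_i)
    # family and member states
    Z <- .ffbs_all(fw$alpha, panel$arm, params$P, panel$n_i)
    if (spec$perception_mode == "identity") {
      Zm <- rep(list(Z), M)
    } else {
      Zm <- vector("list", M)
      zf <- as.vector(Z)
      ok <- which(!is.na(zf))
      for (m in seq_len(M)) {
        Cm <- spec$C_m[m]
        lf <- matrix(lfs[[m]], N * n, Cm)[ok, , drop = FALSE]
        mx <- lf[, 1L]
        if (Cm > 1L) for (k in 2:Cm) mx <- pmax(mx, lf[, k])
        f <- exp(lf - mx)
        if (spec$perception_mode == "shared") {
          pr <- f * params$Q[[m]][zf[ok], , drop = FALSE]
        } else {
          pr <- f
          arms_cell <- panel$arm[((ok - 1L) %% N) + 1L]
          for (s in seq_len(S)) {
            rs <- arms_cell == s
            if (any(rs)) pr[rs, ] <- f[rs, , drop = FALSE] *
                params$Q[[m]][[s]][zf[ok][rs], , drop = FALSE]
          }
        }
        zm <- matrix(NA_integer_, N, n)
        zm[ok] <- .rcat(pr, stats::runif(length(ok)))
        Zm[[m]] <- zm
      }
    }
    # chain probabilities
    cp <- update_chain_probs(Z, panel$arm, S, C, prior$dirichlet_conc)
    params$pi <- cp$pi; params$P <- cp$P
    params$Q <- update_perception(Z, Zm, panel$arm, spec, prior$dirichlet_conc)
    # regression + variances per series
    sig2 <- st$sig2
    if (is.null(fixed_emission)) for (sr in series) {
      m <- sr$m; j <- sr$j; Cm <- spec$C_m[m]
      stt <- as.vector(Zm[[m]])[sr$idx]
      resp <- sr$y - st$b[sr$i, sr$e]
      reg <- update_regression(resp, stt, sig2[[m]][j, ], sr$X,
                               ridge = config$ridge)
      if (reg$jitter > 0) jitter_events <<- jitter_events + 1L
      params$tau[[m]][j, ] <- reg$tau
      if (q > 0) params$beta[[m]][j, ] <- reg$beta
      mu_states <- cumsum(reg$tau)
      fitted <- mu_states[stt] +
        if (q > 0) drop(sr$X %*% reg$beta) else 0
      vr <- update_variances(resp - fitted, stt, Cm,
                             a = prior$ig_shape, b = prior$ig_scale,
                             method = config$variance_param,
                             gamma_current = params$gamma[[m]][j, ],
                             mh_sd = config$mh_sd)
      mh_rejects <<- mh_rejects + vr$rejects
      sig2[[m]][j, ] <- vr$sigma2
      params$gamma[[m]][j, ] <- vr$gamma
    }
    # random effects
    d <- matrix(0, N, r); h <- matrix(0, N, r)
    for (sr in series) {
      m <- sr$m; j <- sr$j
      stt <- as.vector(Zm[[m]])[sr$idx]
      w <- 1 / sig2[[m]][j, ][stt]
      mu_states <- cumsum(params$tau[[m]][j, ])
      fitted <- mu_states[stt] +
        if (q > 0) drop(sr$X %*% params$beta[[m]][j, ]) else 0
      resid0 <- sr$y - fitted
      dsum <- rowsum(cbind(w, w * resid0), sr$i)
      rows <- as.integer(rownames(dsum))
      d[rows, sr$e] <- d[rows, sr$e] + dsum[, 1L]
      h[rows, sr$e] <- h[rows, sr$e] + dsum[, 2L]
    }
    b <- .draw_random_effects(d, h, params$Sigma)
    params$Sigma <- update_sigma(b, prior$iw_df, Sinv_prior_scale)
    st2 <- list(params = params, b = b, Z = Z, Zm = Zm, sig2 = sig2)
    if (config$relabel) {
      perms <- .relabel_perms(params, spec, ref_member = M, ref_outcome = 1L)
      rl <- .apply_relabel(st2, spec, perms)
      if (!is.null(rl)) {
        ok_rl <- TRUE
        if (config$variance_param == "increments")
          ok_rl <- all(unlist(lapply(rl$params$gamma, function(g) g > 0)))
        if (ok_rl) {
          rl$sig2 <- lapply(seq_len(M), function(m)
            .row_cumsum(rl$params$gamma[[m]]))
          st2 <- rl
          relabel_count <<- relabel_count + 1L
        } else relabel_skipped <<- relabel_skipped + 1L
      }
    }
    st2$ll <- if (want_ll) fw$logc else NULL
    st2
  }

  # ---- phase 1 ----
  acc <- NULL; n_acc <- 0L
  for (it in seq_len(config$phase1_iter)) {
    st <- one_iter(st)
    if (it > config$phase1_burn) {
      acc <- .acc_add(acc, st, spec)
      n_acc <- n_acc + 1L
    }
  }
  st <- .acc_restart(acc, n_acc, st, spec)
  if (config$variance_param == "increments") {
    # keep restart values inside the positive-increment prior support
    for (m in seq_len(M)) {
      st$params$gamma[[m]][] <- pmax(st$params$gamma[[m]], 1e-8)
      st$sig2[[m]] <- .row_cumsum(st$params$gamma[[m]])
    }
  }

  # ---- phase 2 ----
  keep_iters <- seq(config$phase2_burn + config$thin, config$phase2_iter,
                    by = config$thin)
  K <- length(keep_iters)
  if (K < 1L) stop("schedule keeps no draws")
  dr <- list(
    pi = array(NA_real_, c(K, S, C)), P = array(NA_real_, c(K, S, C, C)),
    Q = array(NA_real_, c(K, M, if (spec$perception_mode == "arm_specific") S else 1L,
                          C, Cmax)),
    tau = array(NA_real_, c(K, M, Jmax, Cmax)),
    gamma = array(NA_real_, c(K, M, Jmax, Cmax)),
    sigma2 = array(NA_real_, c(K, M, Jmax, Cmax)),
    beta = array(NA_real_, c(K, M, Jmax, max(q, 1L))),
    Sigma = array(NA_real_, c(K, r, r)),
    b = array(NA_real_, c(K, N, r)),
    ll = array(NA_real_, c(K, N, n)))
  if (config$store_latent) {
    dr$Z <- array(NA_integer_, c(K, N, n))
    dr$Zm <- array(NA_integer_, c(K, M, N, n))
  }
  pending <- 0L  # draw slot awaiting its pointwise log-likelihood
  slot <- 0L
  for (it in seq_len(config$phase2_iter)) {
    st <- one_iter(st, want_ll = pending > 0L)
    if (pending > 0L) {
      dr$ll[pending, , ] <- st$ll
      pending <- 0L
    }
    if (it > config$phase2_burn && (it - config$phase2_burn) %% config$thin == 0L) {
      slot <- slot + 1L
      dr <- .store_draw(dr, slot, st, spec, config$store_latent)
      pending <- slot
    }
  }
  if (pending > 0L) {
    # final stored draw: one extra forward pass for its log-likelihood
    lfs <- .logf_members(panel, st$params, st$b)
    logG <- .logG_from_lfs(lfs, st$params, panel, n)
    fw <- .forward_all(logG, panel$arm, st$params$pi, st$params$P, panel$n_i)
    dr$ll[pending, , ] <- fw$logc
  }

  structure(list(
    draws = dr, spec = spec, config = config, n_draws = K,
    panel_info = list(N = N, n = n, n_i = panel$n_i, arm = panel$arm,
                      arm_levels = panel$arm_levels,
                      member_levels = panel$member_levels,
                      outcome_levels = panel$outcome_levels),
    b_last = st$b,
    meta = list(seed = config$seed, relabel_count = relabel_count,
                relabel_skipped = relabel_skipped, mh_rejects = mh_rejects,
                jitter_events = jitter_events,
                elapsed = proc.time()[["elapsed"]] - t0)),
    class = "phmm_fit")
}

# all-cluster draw from the random-effect full conditionals: the cluster
# precision matrices share Sigma^{-1} and differ only in their diagonal,
# so a small Cholesky is unrolled with N-vector operations
.draw_random_effects <- function(d, h, Sigma) {
  N <- nrow(d); r <- ncol(d)
  Sinv <- chol2inv(chol(Sigma))
  L <- array(0, c(N, r, r))  # lower Cholesky of Sinv + diag(d_i), per cluster
  for (j in seq_len(r)) {
    s <- Sinv[j, j] + d[, j]
    if (j > 1L) for (p in seq_len(j - 1L)) s <- s - L[, j, p]^2
    L[, j, j] <- sqrt(s)
    if (j < r) for (k in (j + 1L):r) {
      s <- rep(Sinv[k, j], N)
      if (j > 1L) for (p in seq_len(j - 1L)) s <- s - L[, k, p] * L[, j, p]
      L[, k, j] <- s / L[, j, j]
    }
  }
  v <- matrix(0, N, r)  # L v = h
  for (j in seq_len(r)) {
    s <- h[, j]
    if (j > 1L) for (p in seq_len(j - 1L)) s <- s - L[, j, p] * v[, p]
    v[, j] <- s / L[, j, j]
  }
  z <- matrix(stats::rnorm(N * r), N, r)
  mu <- matrix(0, N, r); x <- matrix(0, N, r)  # L' mu = v ; L' x = z
  for (j in r:1) {
    s1 <- v[, j]; s2 <- z[, j]
    if (j < r) for (p in (j + 1L):r) {
      s1 <- s1 - L[, p, j] * mu[, p]
      s2 <- s2 - L[, p, j] * x[, p]
    }
    mu[, j] <- s1 / L[, j, j]
    x[, j] <- s2 / L[, j, j]
  }
  mu + x
}

# mixture matrix diagonal from precomputed member log-densities
.logG_from_lfs <- function(lfs, params, panel, n) {
  spec <- params$spec
  N <- panel$N; C <- spec$C
  out <- array(0, c(N, n, C))
  for (m in seq_len(spec$M)) {
    lf <- matrix(lfs[[m]], N * n, spec$C_m[m])
    mx <- lf[, 1L]
    if (ncol(lf) > 1L) for (k in 2:ncol(lf)) mx <- pmax(mx, lf[, k])
    f <- exp(lf - mx)
    add <- matrix(0, N * n, C)
    for (s in seq_len(spec$S)) {
      rows <- rep(panel$arm == s, n)
      if (!any(rows)) next
      add[rows, ] <- log(f[rows, , drop = FALSE] %*% t(.get_Q(params, m, s))) +
        mx[rows]
    }
    out <- out + array(add, c(N, n, C))
  }
  out
}

.add_rec <- function(a, b) {
  if (is.list(a)) mapply(.add_rec, a, b, SIMPLIFY = FALSE) else a + b
}

.acc_add <- function(acc, st, spec) {
  flat <- .params_flat(st$params, st$b, spec)
  if (is.null(acc)) flat else .add_rec(acc, flat)
}

.params_flat <- function(params, b, spec) {
  means <- lapply(seq_len(spec$M), function(m)
    .row_cumsum(params$tau[[m]]))
  vars <- lapply(seq_len(spec$M), function(m)
    .row_cumsum(params$gamma[[m]]))
  Qf <- if (spec$perception_mode == "arm_specific")
    unlist(params$Q, recursive = FALSE) else params$Q
  list(pi = params$pi, P = params$P, Q = Qf, means = means, vars = vars,
       beta = params$beta, Sigma = params$Sigma, b = b)
}

.acc_restart <- function(acc, n_acc, st, spec) {
  avg <- rapply(acc, function(x) x / n_acc, how = "replace")
  params <- st$params
  params$pi <- avg$pi / rowSums(avg$pi)
  params$P <- lapply(avg$P, function(p) p / rowSums(p))
  if (spec$perception_mode == "arm_specific") {
    idx <- 0L
    for (m in seq_len(spec$M)) for (s in seq_len(spec$S)) {
      idx <- idx + 1L
      params$Q[[m]][[s]] <- avg$Q[[idx]] / rowSums(avg$Q[[idx]])
    }
  } else if (spec$perception_mode == "shared") {
    params$Q <- lapply(avg$Q, function(q) q / rowSums(q))
  }
  sig2 <- vector("list", spec$M)
  for (m in seq_len(spec$M)) {
    params$tau[[m]] <- .row_decumsum(avg$means[[m]])
    params$gamma[[m]] <- .row_decumsum(avg$vars[[m]])
    params$beta[[m]] <- avg$beta[[m]]
    sig2[[m]] <- avg$vars[[m]]
  }
  params$Sigma <- (avg$Sigma + t(avg$Sigma)) / 2
  list(params = params, b = avg$b, Z = st$Z, Zm = st$Zm, sig2 = sig2)
}

.store_draw <- function(dr, k, st, spec, store_latent) {
  p <- st$params
  dr$pi[k, , ] <- p$pi
  for (s in seq_len(spec$S)) dr$P[k, s, , ] <- p$P[[s]]
  for (m in seq_len(spec$M)) {
    Cm <- spec$C_m[m]
    if (spec$perception_mode == "arm_specific") {
      for (s in seq_len(spec$S)) dr$Q[k, m, s, , seq_len(Cm)] <- p$Q[[m]][[s]]
    } else {
      dr$Q[k, m, 1L, , seq_len(Cm)] <- p$Q[[m]]
    }
    for (j in seq_len(spec$J[m])) {
      dr$tau[k, m, j, seq_len(Cm)] <- p$tau[[m]][j, ]
      dr$gamma[k, m, j, seq_len(Cm)] <- p$gamma[[m]][j, ]
      dr$sigma2[k, m, j, seq_len(Cm)] <- st$sig2[[m]][j, ]
      if (spec$q > 0) dr$beta[k, m, j, seq_len(spec$q)] <- p$beta[[m]][j, ]
    }
  }
  dr$Sigma[k, , ] <- p$Sigma
  dr$b[k, , ] <- st$b
  if (store_latent) {
    dr$Z[k, , ] <- st$Z
    for (m in seq_len(spec$M)) dr$Zm[k, m, , ] <- st$Zm[[m]]
  }
  dr
}

#' @export
print.phmm_fit <- function(x, ...) {
  cat(sprintf("phmm_fit: %s, %d kept draws, %d clusters x %d visits\n",
              x$spec$perception_mode, x$n_draws, x$panel_info$N, x$panel_info$n))
  cat(sprintf("  seed %d, relabel events %d, elapsed %.1fs\n",
              x$meta$seed, x$meta$relabel_count, x$meta$elapsed))
  cat("posterior mean initial probabilities (rows = arms):\n")
  print(round(apply(x$draws$pi, c(2L, 3L), mean), 3))
  invisible(x)
}

#' Posterior summaries of the main parameter blocks
#'
#' @param object A `phmm_fit`.
#' @param ... Unused.
#' @return List of posterior means and 95% credible bounds for `pi`, `P`
#'   and `Q`.
#' @export
summary.phmm_fit <- function(object, ...) {
  qs <- function(a, dims) list(
    mean = apply(a, dims, mean),
    lower = apply(a, dims, stats::quantile, 0.025),
    upper = apply(a, dims, stats::quantile, 0.975))
  out <- list(pi = qs(object$draws$pi, 2:3),
              P = qs(object$draws$P, 2:4),
              Q = qs(object$draws$Q, 2:5))
  class(out) <- "summary.phmm_fit"
  out
}

#' @export
print.summary.phmm_fit <- function(x, ...) {
  cat("initial probabilities (posterior mean; rows = arms):\n")
  print(round(x$pi$mean, 3))
  S <- dim(x$P$mean)[1L]
  for (s in seq_len(S)) {
    cat(sprintf("transition matrix, arm %d (posterior mean):\n", s))
    print(round(matrix(x$P$mean[s, , ], dim(x$P$mean)[2L]), 3))
  }
  M <- dim(x$Q$mean)[1L]; nq <- dim(x$Q$mean)[2L]
  for (m in seq_len(M)) for (s in seq_len(nq)) {
    cat(sprintf("perception matrix, member %d%s (posterior mean):\n", m,
                if (nq > 1L) sprintf(", arm %d", s) else ""))
    qm <- matrix(x$Q$mean[m, s, , ], dim(x$Q$mean)[3L])
    print(round(qm[, colSums(!is.na(qm)) > 0, drop = FALSE], 3))
  }
  invisible(x)
}
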