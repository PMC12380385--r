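# shared fixtures, all generated in code

# random valid parameter set for property-style tests
random_params <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rdir_rows <- function(nr, nc) {
    x <- matrix(rgamma(nr * nc, 1), nr, nc)
    x / rowSums(x)
  }
  pi <- rdir_rows(spec$S, spec$C)
  P <- lapply(seq_len(spec$S), function(s) rdir_rows(spec$C, spec$C))
  Q <- if (spec$perception_mode == "identity") NULL
  else if (spec$perception_mode == "shared")
    lapply(seq_len(spec$M), function(m) rdir_rows(spec$C, spec$C_m[m]))
  else lapply(seq_len(spec$M), function(m)
    lapply(seq_len(spec$S), function(s) rdir_rows(spec$C, spec$C_m[m])))
  tau <- lapply(seq_len(spec$M), function(m)
    matrix(rnorm(spec$J[m] * spec$C_m[m], 0, 2), spec$J[m]))
  gamma <- lapply(seq_len(spec$M), function(m) {
    g <- matrix(rgamma(spec$J[m] * spec$C_m[m], 3, 2) + 0.2, spec$J[m])
    # increments of positive cumulative variances
    for (j in seq_len(spec$J[m])) g[j, ] <- diff(c(0, cumsum(g[j, ])))
    g
  })
  beta <- lapply(seq_len(spec$M), function(m)
    matrix(rnorm(spec$J[m] * spec$q, 0, 0.5), spec$J[m], spec$q))
  A <- matrix(rnorm(spec$r^2), spec$r)
  Sigma <- crossprod(A) / spec$r + diag(spec$r) * 0.5
  phmm_params(spec, pi = pi, P = P, Q = Q, tau = tau, beta = beta,
              gamma = gamma, Sigma = Sigma)
}

# tiny long-format data frame for panel tests
toy_long_df <- function() {
  g <- expand.grid(cluster_id = c("f1", "f2"), visit = 1:3,
                   member = c("child", "parent"), outcome_idx = 1:2,
                   stringsAsFactors = FALSE)
  g$outcome <- ifelse(g$member == "child",
                      c("CDFR", "CPCC")[g$outcome_idx],
                      c("PDFR", "PPCC")[g$outcome_idx])
  g$arm <- ifelse(g$cluster_id == "f1", "usual-care", "intervention")
  set.seed(42)
  g$value <- round(rnorm(nrow(g), 30, 3), 3)
  g$age <- ifelse(g$cluster_id == "f1", 11.2, 13.4)
  g$gender <- ifelse(g$cluster_id == "f1", 1, 0)
  g[order(g$cluster_id, g$visit, g$member, g$outcome),
    c("cluster_id", "visit", "arm", "member", "outcome", "value",
      "age", "gender")]
}

# brute-force marginal likelihood by path enumeration (independent oracle)
enumerate_loglik <- function(panel, params, b, g_form = "generative") {
  spec <- params$spec
  out <- numeric(panel$N)
  for (i in seq_len(panel$N)) {
    n_i <- panel$n_i[i]; s <- panel$arm[i]
    Gv <- matrix(0, n_i, spec$C)
    for (t in seq_len(n_i)) {
      gv <- rep(1, spec$C)
      for (m in seq_len(spec$M)) {
        y_m <- panel$y[i, t, m, seq_len(spec$J[m])]
        x <- if (spec$q > 0) panel$X[i, t, ] else NULL
        bm <- b[i, vapply(seq_len(spec$J[m]),
                          function(j) perceptHMM:::.global_index(spec$J, m, j), 1L)]
        gv <- gv * member_mixture_vector(y_m, perceptHMM:::.get_Q(params, m, s),
                                         params$tau[[m]], params$gamma[[m]],
                                         x = x, beta = params$beta[[m]],
                                         b = bm, g_form = g_form)
      }
      Gv[t, ] <- gv
    }
    paths <- as.matrix(expand.grid(rep(list(seq_len(spec$C)), n_i)))
    tot <- 0
    for (p in seq_len(nrow(paths))) {
      z <- paths[p, ]
      pr <- params$pi[s, z[1L]] * Gv[1L, z[1L]]
      if (n_i > 1L) for (t in 2:n_i)
        pr <- pr * params$P[[s]][z[t - 1L], z[t]] * Gv[t, z[t]]
      tot <- tot + pr
    }
    out[i] <- log(tot)
  }
  out
}

# small simulated panel + short fit, shared by diagnostics/summaries tests;
# built once per test run
fixture_fit_env <- new.env()
fixture_fit <- function() {
  if (!is.null(fixture_fit_env$fit)) return(fixture_fit_env$fit)
  # N below the trial size keeps the suite fast; the inverse-Wishart prior
  # with identity scale inflates the small log-PCC random-effect variances
  # noticeably below a few hundred clusters, so N = 250 balances runtime
  # against that prior effect
  preset <- scenario_preset(2, N = 250L, n = 5L)
  sim <- simulate_dataset(preset, seed = 99L)
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "shared")
  cfg <- sampler_config(phase1_iter = 150L, phase1_burn = 70L,
                        phase2_iter = 600L, phase2_burn = 240L,
                        thin = 2L, seed = 5L)
  fit <- run_sampler(sim$panel, spec, cfg)
  fixture_fit_env$fit <- fit
  fixture_fit_env$sim <- sim
  fit
}
fixture_sim <- function() {
  fixture_fit()
  fixture_fit_env$sim
}
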