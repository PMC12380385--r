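# Joint-distribution (successive-conditional) check of the sampler's
# chain-probability and perception updates: alternating "simulate data
# given parameters" with one Gibbs transition "sample states then
# parameters given data" must leave the Dirichlet prior marginals of
# pi, P and Q invariant. Emission parameters and Sigma are held fixed.
# Returns a matrix of draws (columns: pi/P/Q entries).
#' @noRd
.geweke_chain <- function(C = 2L, N = 20L, n = 3L, n_iter = 2000L, seed = 1L,
                          state_means = c(-2, 2), state_vars = c(1, 1),
                          re_var = 0.25, conc = 1) {
  set.seed(seed)
  spec <- model_spec(C = C, M = 1L, J = 1L, S = 1L, q = 0L,
                     perception_mode = "shared")
  tau <- list(matrix(diff(c(0, state_means)), 1L, C))
  gamma <- list(matrix(diff(c(0, state_vars)), 1L, C))
  Sigma <- matrix(re_var, 1L, 1L)
  draw_prior <- function() {
    list(pi = matrix(.rdirichlet(rep(conc, C)), 1L),
         P = list(.rdirichlet_rows(matrix(conc, C, C))),
         Q = list(.rdirichlet_rows(matrix(conc, C, C))))
  }
  th <- draw_prior()
  params <- phmm_params(spec, pi = th$pi, P = th$P, Q = th$Q,
                        tau = tau, gamma = gamma, Sigma = Sigma)
  ncol_out <- C + C * C + C * C
  out <- matrix(NA_real_, n_iter, ncol_out)
  colnames(out) <- c(sprintf("pi%d", 1:C),
                     as.vector(outer(1:C, 1:C, function(k, j) sprintf("P%d%d", k, j))),
                     as.vector(outer(1:C, 1:C, function(k, j) sprintf("Q%d%d", k, j))))
  arm <- rep(1L, N)
  mom <- list(means = cumsum(tau[[1L]][1L, ]), vars = cumsum(gamma[[1L]][1L, ]))
  for (it in seq_len(n_iter)) {
    # data | parameters (fresh latents from the prior each sweep)
    b <- stats::rnorm(N, 0, sqrt(re_var))
    Z <- t(vapply(seq_len(N), function(i)
      simulate_family_chain(params$pi[1L, ], params$P[[1L]], n), integer(n)))
    Zm <- matrix(0L, N, n)
    for (i in seq_len(N))
      Zm[i, ] <- drop(simulate_member_states(Z[i, ], params$Q[[1L]]))
    y <- matrix(stats::rnorm(N * n, mom$means[Zm] + b,
                             sqrt(mom$vars[Zm])), N, n)
    # one Gibbs transition: states | y, then (pi, P, Q) | states
    logf <- array(0, c(N, n, C))
    for (k in seq_len(C))
      logf[, , k] <- stats::dnorm(y, mom$means[k] + b, sqrt(mom$vars[k]),
                                  log = TRUE)
    logG <- array(0, c(N, n, C))
    for (h in seq_len(C)) {
      mix <- matrix(0, N, n)
      for (k in seq_len(C))
        mix <- mix + params$Q[[1L]][h, k] * exp(logf[, , k])
      logG[, , h] <- log(mix)
    }
    fw <- .forward_all(logG, arm, params$pi, params$P, rep(n, N))
    Zs <- .ffbs_all(fw$alpha, arm, params$P, rep(n, N))
    Zms <- matrix(0L, N, n)
    for (i in seq_len(N))
      Zms[i, ] <- sample_member_states(matrix(logf[i, , ], n, C), Zs[i, ],
                                       params$Q[[1L]])
    cp <- update_chain_probs(Zs, arm, 1L, C, conc)
    params$pi <- cp$pi; params$P <- cp$P
    params$Q <- update_perception(Zs, list(Zms), arm, spec, conc)
    out[it, ] <- c(params$pi[1L, ], as.vector(params$P[[1L]]),
                   as.vector(params$Q[[1L]]))
  }
  out
}
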