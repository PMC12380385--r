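test_that("emission log-density matches closed forms and skips missing cells", {
  # standard normal at zero
  expect_equal(emission_logpdf(0, 1, tau = 0, gamma = 1),
               -0.9189385, tolerance = 1e-6)
  # evaluated exactly at the mean: tau=(1,2) k=2, x'beta=0.5, b=0.25,
  # gamma=(1,3) -> N(3.75; 3.75, 4)
  expect_equal(emission_logpdf(3.75, 2, tau = c(1, 2), gamma = c(1, 3),
                               x = 1, beta = 0.5, b = 0.25),
               -0.5 * log(8 * pi), tolerance = 1e-12)
  # missing cell contributes log 1
  expect_equal(emission_logpdf(NA_real_, 2, tau = c(1, 2), gamma = c(1, 3)), 0)
  # independent scalar recomputation on random inputs
  set.seed(1)
  for (rep in 1:20) {
    tau <- rnorm(3); gam <- rgamma(3, 2) + 0.1
    k <- sample.int(3, 1); y <- rnorm(1, 0, 3); b <- rnorm(1)
    mu <- sum(tau[1:k]) + b
    v <- sum(gam[1:k])
    byhand <- -0.5 * log(2 * pi * v) - (y - mu)^2 / (2 * v)
    expect_equal(emission_logpdf(y, k, tau, gam, b = b), byhand,
                 tolerance = 1e-12)
  }
  expect_error(emission_logpdf(0, 2, tau = c(0, 0), gamma = c(1, -2)),
               "variance")
})

test_that("member mixture vector marginalizes the perceived state correctly", {
  # identity perception reduces to the plain emission product
  tau <- rbind(c(0, 1), c(2, -1)); gam <- rbind(c(1, 0.5), c(2, 0.2))
  y <- c(0.3, 1.7)
  v <- member_mixture_vector(y, diag(2), tau, gam)
  direct <- vapply(1:2, function(h)
    exp(emission_logpdf(y[1], h, tau[1, ], gam[1, ]) +
        emission_logpdf(y[2], h, tau[2, ], gam[2, ])), 0)
  expect_equal(v, direct, tolerance = 1e-12)

  # two-state, one-outcome symbolic expansion
  Q <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  v2 <- member_mixture_vector(0.5, Q, tau[1, , drop = FALSE],
                              gam[1, , drop = FALSE])
  f1 <- exp(emission_logpdf(0.5, 1, tau[1, ], gam[1, ]))
  f2 <- exp(emission_logpdf(0.5, 2, tau[1, ], gam[1, ]))
  expect_equal(v2, c(0.7 * f1 + 0.3 * f2, 0.2 * f1 + 0.8 * f2),
               tolerance = 1e-12)

  # point-mass perception row selects a single state density
  Q3 <- rbind(c(1, 0), c(0, 1))
  v3 <- member_mixture_vector(0.5, Q3, tau[1, , drop = FALSE],
                              gam[1, , drop = FALSE])
  expect_equal(v3[1], f1, tolerance = 1e-12)

  # an all-missing member-visit contributes a vector of ones
  v4 <- member_mixture_vector(c(NA_real_, NA_real_), Q, tau, gam)
  expect_equal(v4, c(1, 1))
})

test_that("forward recursion equals brute-force path enumeration", {
  set.seed(2)
  for (rep in 1:12) {
    C <- sample(1:3, 1); n <- sample(1:4, 1)
    spec <- model_spec(C, M = 2, J = c(2, 1), S = 2, q = 1,
                       perception_mode = "shared")
    params <- random_params(spec)
    N <- 3L
    sim_panel <- local({
      y <- array(rnorm(N * n * 2 * 2, 0, 2), c(N, n, 2, 2))
      y[, , 2, 2] <- NA  # member 2 has one outcome
      if (rep %% 2 == 0) y[1, 1, 1, 1] <- NA  # a missing cell
      X <- array(rnorm(N * n), c(N, n, 1))
      structure(list(y = y, X = X, arm = c(1L, 2L, 1L), n_i = rep(n, N),
                     N = N, M = 2L, J = c(2L, 1L), S = 2L, q = 1L,
                     cluster_ids = 1:N, arm_levels = c("a", "b"),
                     member_levels = c("m1", "m2"),
                     outcome_levels = list(c("o1", "o2"), "o3"),
                     visit_labels = rep(list(seq_len(n)), N),
                     covariates = "x", transforms = list()),
                class = "phmm_panel")
    })
    b <- matrix(rnorm(N * 3, 0, 0.5), N, 3)
    ll <- loglik_conditional(sim_panel, params, b)
    oracle <- enumerate_loglik(sim_panel, params, b)
    expect_equal(ll, oracle, tolerance = 1e-9)
    # printed-form mode agrees with its own enumeration too
    llp <- loglik_conditional(sim_panel, params, b, g_form = "printed")
    oraclep <- enumerate_loglik(sim_panel, params, b, g_form = "printed")
    expect_equal(llp, oraclep, tolerance = 1e-9)
  }
})

test_that("identity perception reproduces the plain mixed HMM likelihood", {
  spec_p <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 0,
                       perception_mode = "shared")
  spec_i <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 0,
                       perception_mode = "identity")
  params_p <- random_params(spec_p, seed = 3)
  params_p$Q <- list(diag(3), diag(3))
  params_i <- phmm_params(spec_i, pi = params_p$pi, P = params_p$P,
                          tau = params_p$tau, gamma = params_p$gamma,
                          Sigma = params_p$Sigma)
  sim <- simulate_dataset(scenario_preset(1, N = 15, n = 4), seed = 4)
  pan <- sim$panel; pan$X <- array(0, c(15, 4, 0)); pan$q <- 0L
  b <- matrix(rnorm(15 * 4, 0, 0.3), 15, 4)
  expect_equal(loglik_conditional(pan, params_p, b),
               loglik_conditional(pan, params_i, b), tolerance = 1e-12)
})

test_that("likelihood is invariant under simultaneous state relabeling", {
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 0,
                     perception_mode = "shared")
  params <- random_params(spec, seed = 5)
  sim <- simulate_dataset(scenario_preset(2, N = 10, n = 3), seed = 6)
  pan <- sim$panel; pan$X <- array(0, c(10, 3, 0)); pan$q <- 0L
  pan$y <- pan$y[, 1:3, , , drop = FALSE]; pan$n_i <- rep(3L, 10)
  b <- matrix(0, 10, 4)
  ll0 <- loglik_conditional(pan, params, b)
  perm <- c(3L, 1L, 2L)
  permuted <- params
  permuted$pi <- params$pi[, perm]
  permuted$P <- lapply(params$P, function(p) p[perm, perm])
  permuted$Q <- lapply(params$Q, function(q) q[perm, ])
  expect_equal(loglik_conditional(pan, permuted, b), ll0, tolerance = 1e-10)
})

test_that("forward scaling constants reconstruct the unscaled recursion", {
  spec <- model_spec(2, M = 1, J = 1, S = 1, q = 0,
                     perception_mode = "shared")
  params <- random_params(spec, seed = 7)
  n <- 3L
  pan <- structure(list(y = array(rnorm(n), c(1, n, 1, 1)),
                        X = array(0, c(1, n, 0)), arm = 1L, n_i = n, N = 1L,
                        M = 1L, J = 1L, S = 1L, q = 0L, cluster_ids = 1L,
                        arm_levels = "a", member_levels = "m",
                        outcome_levels = list("o"),
                        visit_labels = list(1:n), transforms = list(),
                        covariates = character(0)), class = "phmm_panel")
  fw <- forward_filter(pan, params, 1, b = 0)
  expect_equal(rowSums(fw$alpha), rep(1, n))
  # unscaled alpha via direct recursion
  Gv <- vapply(seq_len(n), function(t)
    member_mixture_vector(pan$y[1, t, 1, 1], params$Q[[1]],
                          params$tau[[1]], params$gamma[[1]]),
    numeric(2))
  a_un <- params$pi[1, ] * Gv[, 1]
  for (t in 2:n) a_un <- drop(a_un %*% params$P[[1]]) * Gv[, t]
  expect_equal(fw$loglik, log(sum(a_un)), tolerance = 1e-10)
  expect_equal(fw$alpha[n, ] * exp(sum(fw$log_scale)), a_un,
               tolerance = 1e-10)
})

test_that("single-state likelihood is the sum of cell log-densities", {
  spec <- model_spec(1, M = 2, J = c(2, 2), S = 1, q = 0,
                     perception_mode = "shared")
  params <- random_params(spec, seed = 8)
  n <- 4L
  y <- array(rnorm(n * 4), c(1, n, 2, 2))
  pan <- structure(list(y = y, X = array(0, c(1, n, 0)), arm = 1L, n_i = n,
                        N = 1L, M = 2L, J = c(2L, 2L), S = 1L, q = 0L,
                        cluster_ids = 1L, arm_levels = "a",
                        member_levels = c("c", "p"),
                        outcome_levels = list(c("a1", "a2"), c("b1", "b2")),
                        visit_labels = list(1:n), transforms = list(),
                        covariates = character(0)), class = "phmm_panel")
  total <- 0
  for (m in 1:2) for (j in 1:2) for (t in 1:n)
    total <- total + emission_logpdf(y[1, t, m, j], 1,
                                     params$tau[[m]][j, ],
                                     params$gamma[[m]][j, ])
  expect_equal(loglik_conditional(pan, params, matrix(0, 1, 4)), total,
               tolerance = 1e-10)
})

test_that("Monte Carlo marginal likelihood matches the conjugate closed form", {
  # C = 1, one outcome: y_t | b ~ N(tau + b, gamma), b ~ N(0, s2), so the
  # joint marginal is multivariate normal with covariance gamma*I + s2*J
  spec <- model_spec(1, M = 1, J = 1, S = 1, q = 0, perception_mode = "shared")
  tau <- 1.5; gam <- 0.8; s2 <- 0.6; n <- 3L
  params <- phmm_params(spec, pi = 1, P = matrix(1), Q = list(matrix(1)),
                        tau = list(matrix(tau)), gamma = list(matrix(gam)),
                        Sigma = matrix(s2))
  set.seed(9)
  y <- rnorm(n, tau, sqrt(gam + s2))
  pan <- structure(list(y = array(y, c(1, n, 1, 1)), X = array(0, c(1, n, 0)),
                        arm = 1L, n_i = n, N = 1L, M = 1L, J = 1L, S = 1L,
                        q = 0L, cluster_ids = 1L, arm_levels = "a",
                        member_levels = "m", outcome_levels = list("o"),
                        visit_labels = list(1:n), transforms = list(),
                        covariates = character(0)), class = "phmm_panel")
  V <- gam * diag(n) + s2
  closed <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
                      drop((y - tau) %*% solve(V, y - tau)))
  set.seed(10)
  mc <- marginal_loglik(pan, params, n_mc = 20000L)
  expect_equal(mc, closed, tolerance = 0.02)
  # degenerate mixing: marginal equals conditional at b = 0
  params0 <- params; params0$Sigma <- matrix(1e-12)
  expect_equal(marginal_loglik(pan, params0, n_mc = 50),
               loglik_conditional(pan, params0, matrix(0, 1, 1)),
               tolerance = 1e-4)
  # conditional on supplied b: plain additivity over clusters
  expect_equal(marginal_loglik(pan, params, b = matrix(0.2, 1, 1)),
               loglik_conditional(pan, params, matrix(0.2, 1, 1)))
})

test_that("a vanishing total likelihood is reported, not propagated", {
  # the initial distribution puts all mass on a state whose emission
  # probability underflows against the observation, so the forward
  # probability vector vanishes at the first visit
  spec <- model_spec(2, M = 1, J = 1, S = 1, q = 0,
                     perception_mode = "shared")
  params <- phmm_params(spec, pi = c(0, 1),
                        P = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                        Q = list(diag(2)),
                        tau = list(matrix(c(0, 1e6), 1)),
                        gamma = list(matrix(c(1, 0), 1)),
                        Sigma = matrix(1))
  pan <- structure(list(y = array(0, c(1, 1, 1, 1)),
                        X = array(0, c(1, 1, 0)), arm = 1L, n_i = 1L,
                        N = 1L, M = 1L, J = 1L, S = 1L, q = 0L,
                        cluster_ids = 1L, arm_levels = "a",
                        member_levels = "m", outcome_levels = list("o"),
                        visit_labels = list(1L), transforms = list(),
                        covariates = character(0)), class = "phmm_panel")
  fw <- forward_filter(pan, params, 1)
  expect_identical(fw$loglik, -Inf)
  expect_match(fw$diagnostic, "visit 1")
})
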