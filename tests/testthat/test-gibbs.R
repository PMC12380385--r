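test_that("chain-probability update has the exact conjugate form", {
  # a single arm, counts 2/3/5 out of state 1
  Z <- rbind(cbind(rep(1L, 10), c(rep(1L, 2), rep(2L, 3), rep(3L, 5))))
  cond <- update_chain_probs(Z, arm = rep(1L, 10), S = 1, C = 3,
                             conditional = TRUE)
  expect_equal(cond$P_alpha[1, 1, ], c(3, 4, 6))
  expect_equal(cond$pi_alpha[1, ], c(11, 1, 1))
  # zero data falls back to the prior
  Zna <- matrix(NA_integer_, 2, 2)
  cond0 <- update_chain_probs(Zna, arm = c(1L, 1L), S = 1, C = 3,
                              conditional = TRUE)
  expect_equal(cond0$pi_alpha[1, ], c(1, 1, 1))
  set.seed(1)
  draws <- t(replicate(4000, update_chain_probs(Zna, c(1L, 1L), 1, 3)$pi[1, ]))
  expect_equal(colMeans(draws), rep(1 / 3, 3), tolerance = 0.03)
  # conjugacy oracle: posterior mean of a large-count row approaches the
  # empirical transition rate
  set.seed(2)
  big <- matrix(sample.int(3, 2e4, replace = TRUE, prob = c(0.2, 0.3, 0.5)),
                ncol = 2)
  cond2 <- update_chain_probs(big, rep(1L, nrow(big)), 1, 3,
                              conditional = TRUE)
  emp <- tabulate(big[big[, 1] == 2L, 2L], 3)
  expect_equal(unname(cond2$P_alpha[1, 2, ]), 1 + emp)
})

test_that("perception update pools counts correctly by mode", {
  spec_sh <- model_spec(2, M = 1, J = 1, S = 2, perception_mode = "shared")
  spec_as <- model_spec(2, M = 1, J = 1, S = 2,
                        perception_mode = "arm_specific")
  Z <- rbind(c(1L, 1L), c(2L, 2L), c(1L, 2L), c(2L, 1L))
  Zm <- list(rbind(c(1L, 2L), c(2L, 2L), c(1L, 1L), c(2L, 2L)))
  arm <- c(1L, 1L, 2L, 2L)
  sh <- update_perception(Z, Zm, arm, spec_sh, conditional = TRUE)
  as_ <- update_perception(Z, Zm, arm, spec_as, conditional = TRUE)
  # shared counts are the sum of per-arm counts (prior counted once)
  expect_equal(sh[[1]], as_[[1]][[1]] + as_[[1]][[2]] - 1)
  # identity mode returns the identity without sampling
  spec_id <- model_spec(2, M = 1, J = 1, S = 2, perception_mode = "identity")
  expect_equal(update_perception(Z, Zm, arm, spec_id), list(diag(2)))
  # closed form for a clean cross-count table
  Zc <- matrix(rep(c(1L, 2L), each = 10), ncol = 1)
  Zmc <- list(Zc)
  cond <- update_perception(Zc, Zmc, rep(1L, 20),
                            model_spec(2, M = 1, J = 1, S = 1,
                                       perception_mode = "shared"),
                            conditional = TRUE)
  expect_equal(cond[[1]], rbind(c(11, 1), c(1, 11)))
})

test_that("regression update reproduces weighted least squares exactly", {
  # noiseless single-state data: posterior degenerates onto the sample mean
  y <- rep(2.5, 30)
  cond <- update_regression(y, rep(1L, 30), sigma2 = c(1), conditional = TRUE)
  expect_equal(cond$mean, 2.5, tolerance = 1e-10)
  expect_equal(cond$cov[1, 1], 1 / 30, tolerance = 1e-10)

  # cumulative encoding reproduces per-state means via prefix sums
  states <- rep(1:3, each = 50)
  mus <- c(1, 4, 2)
  y3 <- mus[states]
  cond3 <- update_regression(y3, states, sigma2 = rep(1, 3),
                             conditional = TRUE)
  expect_equal(cumsum(cond3$mean), mus, tolerance = 1e-8)

  # agreement with an independent generalized-least-squares computation
  set.seed(3)
  states <- sample.int(3, 200, replace = TRUE)
  X <- cbind(rnorm(200), rbinom(200, 1, 0.5))
  sig2 <- c(0.5, 1, 2)
  y <- rnorm(200, 0, 1)
  cond <- update_regression(y, states, sig2, X, conditional = TRUE)
  W <- cbind(outer(states, 1:3, ">=") * 1, X)
  V <- diag(1 / sig2[states])
  A <- t(W) %*% V %*% W
  expect_equal(cond$mean, drop(solve(A, t(W) %*% V %*% y)), tolerance = 1e-8)
  expect_equal(cond$cov, solve(A), tolerance = 1e-8)

  # a never-visited state triggers the ridge fallback instead of failing
  cond_rd <- update_regression(y[states != 3], states[states != 3],
                               sig2, conditional = TRUE)
  expect_gt(cond_rd$jitter, 0)
})

test_that("variance updates match the conjugate closed form and the two samplers agree", {
  # residual SS 10 over 20 cells with the trial prior
  resid <- sqrt(rep(0.5, 20))
  cond <- update_variances(resid, rep(1L, 20), C = 1, a = 0.001, b = 0.0002,
                           conditional = TRUE)
  expect_equal(cond$shape, 10.001)
  expect_equal(cond$scale, 5.0002)

  # direct-mode posterior concentrates on the generating variance
  set.seed(4)
  res <- rnorm(2e4, 0, sqrt(2.5))
  cond2 <- update_variances(res, rep(1L, 2e4), C = 1, conditional = TRUE)
  expect_equal(cond2$scale / (cond2$shape - 1), 2.5, tolerance = 0.05)

  # increments-mode stationary distribution matches direct mode when the
  # truth has increasing variances (one-outcome toy, long MH run)
  set.seed(5)
  states <- sample.int(2, 4000, replace = TRUE)
  vars_true <- c(1, 3)
  res2 <- rnorm(4000, 0, sqrt(vars_true[states]))
  gam <- c(1, 1)
  draws_inc <- matrix(0, 400, 2)
  for (it in 1:400) {
    up <- update_variances(res2, states, C = 2, method = "increments",
                           gamma_current = gam, mh_sd = 0.15)
    gam <- up$gamma
    draws_inc[it, ] <- up$sigma2
  }
  direct_mean <- sapply(1:2, function(k) {
    cd <- update_variances(res2[states == k], rep(1L, sum(states == k)),
                           C = 1, conditional = TRUE)
    cd$scale / (cd$shape - 1)
  })
  expect_equal(colMeans(draws_inc[101:400, ]), direct_mean, tolerance = 0.1)
})

test_that("random-effect update matches normal-normal shrinkage", {
  Sigma <- diag(c(4, 4))
  # no observations: the prior is returned
  cond0 <- update_random_effects(c(0, 0), c(0, 0), Sigma, conditional = TRUE)
  expect_equal(cond0$mean, c(0, 0))
  expect_equal(cond0$cov, Sigma, tolerance = 1e-10)
  # one cell per outcome, independent prior: classical shrinkage
  yobs <- c(2, -1); s2 <- c(1, 2)
  cond <- update_random_effects(1 / s2, yobs / s2, Sigma, conditional = TRUE)
  expect_equal(cond$mean, (yobs / s2) / (1 / 4 + 1 / s2), tolerance = 1e-10)
  # grid oracle on a correlated 2-d toy
  Sig <- rbind(c(1, 0.6), c(0.6, 2))
  d <- c(2.0, 0.5); h <- c(1.2, -0.4)
  cond2 <- update_random_effects(d, h, Sig, conditional = TRUE)
  A <- solve(Sig) + diag(d)
  expect_equal(cond2$mean, drop(solve(A, h)), tolerance = 1e-10)
  expect_equal(cond2$cov, solve(A), tolerance = 1e-10)
})

test_that("covariance update follows the inverse-Wishart closed form", {
  b0 <- matrix(0, 0, 3)
  cond0 <- update_sigma(b0, df = 4, scale = diag(3), conditional = TRUE)
  expect_equal(cond0$df, 4)
  expect_equal(cond0$scale, diag(3))
  set.seed(6)
  b <- matrix(rnorm(12), 4, 3)
  cond <- update_sigma(b, df = 4, scale = diag(3), conditional = TRUE)
  expect_equal(cond$scale, diag(3) + t(b) %*% b, tolerance = 1e-12)
  expect_equal(cond$df, 8)
  # consistency: with many clusters the draw concentrates near the truth
  set.seed(7)
  S0 <- rbind(c(2, 0.5), c(0.5, 1))
  bN <- matrix(rnorm(2e4), ncol = 2) %*% chol(S0)
  draw <- update_sigma(bN, df = 3, scale = diag(2))
  expect_equal(draw, S0, tolerance = 0.1)
})

test_that("family-state FFBS draws from the exact path conditional", {
  # two-state, two-visit toy: enumerate the conditional over 4 paths
  pi0 <- c(0.6, 0.4)
  P <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  logG <- rbind(log(c(0.9, 0.3)), log(c(0.2, 0.8)))
  joint <- matrix(0, 2, 2)
  for (z1 in 1:2) for (z2 in 1:2)
    joint[z1, z2] <- pi0[z1] * exp(logG[1, z1]) * P[z1, z2] * exp(logG[2, z2])
  joint <- joint / sum(joint)
  set.seed(8)
  nrep <- 20000L
  counts <- matrix(0, 2, 2)
  for (rp in seq_len(nrep)) {
    z <- ffbs_family_states(logG, pi0, P)
    counts[z[1], z[2]] <- counts[z[1], z[2]] + 1
  }
  freq <- counts / nrep
  for (idx in 1:4) {
    se <- sqrt(joint[idx] * (1 - joint[idx]) / nrep)
    expect_lt(abs(freq[idx] - joint[idx]), 4 * se)
  }
  # single state: everything is state 1
  expect_equal(ffbs_family_states(matrix(0, 4, 1), 1, matrix(1)), rep(1L, 4))
  # point-mass emissions separate states perfectly
  logG2 <- rbind(c(0, -1e8), c(-1e8, 0), c(0, -1e8))
  expect_equal(ffbs_family_states(logG2, c(0.5, 0.5),
                                  rbind(c(0.5, 0.5), c(0.5, 0.5))),
               c(1L, 2L, 1L))
})

test_that("member-state sampling follows its enumerated conditional", {
  Q <- rbind(c(0.7, 0.3), c(0.1, 0.9))
  logf <- matrix(log(c(0.5, 0.2)), 1)
  # exact conditional for family state 1
  p1 <- Q[1, ] * c(0.5, 0.2); p1 <- p1 / sum(p1)
  set.seed(9)
  draws <- replicate(20000, sample_member_states(logf, 1L, Q))
  fr <- mean(draws == 1L)
  expect_lt(abs(fr - p1[1]), 4 * sqrt(p1[1] * (1 - p1[1]) / 20000))
  # identity perception copies the family state
  expect_equal(sample_member_states(logf, 2L, diag(2)), 2L)
  # flat perception with equal emissions is uniform
  set.seed(10)
  u <- replicate(5000, sample_member_states(matrix(0, 1, 2), 1L,
                                            rbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_lt(abs(mean(u == 1L) - 0.5), 0.03)
})

test_that("the sampler is deterministic given a seed and draws validate", {
  sim <- simulate_dataset(scenario_preset(2, N = 30), seed = 11)
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "shared")
  cfg <- sampler_config(phase1_iter = 40, phase1_burn = 20,
                        phase2_iter = 80, phase2_burn = 40, thin = 2,
                        seed = 12)
  f1 <- run_sampler(sim$panel, spec, cfg)
  f2 <- run_sampler(sim$panel, spec, cfg)
  expect_identical(f1$draws$pi, f2$draws$pi)
  expect_identical(f1$draws$Z, f2$draws$Z)
  # stored draws are valid parameter sets
  for (k in c(1L, f1$n_draws)) {
    pk <- perceptHMM:::.params_from_draw(f1, k)
    expect_identical(validate_params(pk), character(0))
  }
  # schedule bookkeeping
  expect_equal(f1$n_draws, 20L)
})

test_that("increments-mode sampler runs and respects positivity", {
  sim <- simulate_dataset(scenario_preset(1, N = 25), seed = 13)
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "identity")
  cfg <- sampler_config(phase1_iter = 30, phase1_burn = 15,
                        phase2_iter = 60, phase2_burn = 30, thin = 2,
                        seed = 14, variance_param = "increments")
  fit <- run_sampler(sim$panel, spec, cfg)
  expect_true(all(fit$draws$gamma[, , , ] >= 0, na.rm = TRUE))
  expect_true(all(apply(fit$draws$sigma2, 1, function(x) all(x > 0, na.rm = TRUE))))
})

test_that("the joint-distribution (prior invariance) check passes on a tiny model", {
  dr <- perceptHMM:::.geweke_chain(C = 2L, N = 20L, n = 3L, n_iter = 2500L,
                                   seed = 15)
  # Dirichlet(1,1) rows make every entry marginally Uniform(0,1)
  # the successive-conditional chain is autocorrelated, so decile
  # agreement is asserted with a correspondingly loose band
  for (cn in c("pi1", "P11", "P21", "Q11", "Q21")) {
    dec <- quantile(dr[, cn], probs = (1:9) / 10, names = FALSE)
    expect_lt(max(abs(dec - (1:9) / 10)), 0.1)
  }
})

test_that("the arm-specific perception model fits scenario-3 data", {
  sim <- simulate_dataset(scenario_preset(3, N = 30), seed = 16)
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "arm_specific")
  cfg <- sampler_config(phase1_iter = 40, phase1_burn = 20,
                        phase2_iter = 100, phase2_burn = 50, thin = 2,
                        seed = 17)
  fit <- run_sampler(sim$panel, spec, cfg)
  expect_equal(dim(fit$draws$Q), c(25L, 2L, 2L, 3L, 3L))
  pk <- perceptHMM:::.params_from_draw(fit, fit$n_draws)
  expect_identical(validate_params(pk), character(0))
  # arm-specific contrasts are computable per arm
  pc <- perception_contrasts(fit, arm = 2L)
  expect_equal(nrow(pc), 9L)
})
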