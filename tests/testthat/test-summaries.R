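test_that("stationary distribution matches a power-iteration oracle", {
  # doubly stochastic: uniform stationary law
  P <- rbind(c(0.2, 0.3, 0.5), c(0.5, 0.2, 0.3), c(0.3, 0.5, 0.2))
  expect_equal(stationary_distribution(P), rep(1 / 3, 3), tolerance = 1e-10)
  set.seed(1)
  for (rep in 1:10) {
    Pr <- matrix(rgamma(9, 1), 3); Pr <- Pr / rowSums(Pr)
    s <- stationary_distribution(Pr)
    power <- rep(1 / 3, 3)
    for (k in 1:4000) power <- drop(power %*% Pr)
    expect_equal(s, power, tolerance = 1e-10)
    expect_equal(drop(s %*% Pr), s, tolerance = 1e-10)
  }
  # identity chain is reducible: flagged, limiting average returned
  expect_warning(s_id <- stationary_distribution(diag(3)), "reducible")
  expect_equal(sum(s_id), 1)
  expect_error(stationary_distribution(rbind(c(0.5, 0.6), c(0.5, 0.5))),
               "probability")
})

fake_fit_probs <- function(P_draws, Q_draws = NULL, spec) {
  K <- dim(P_draws)[1L]
  structure(list(draws = list(P = P_draws,
                              pi = array(1 / spec$C, c(K, spec$S, spec$C)),
                              Q = Q_draws),
                 spec = spec, n_draws = K), class = "phmm_fit")
}

test_that("arm contrasts are centered at zero when arms share parameters", {
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, perception_mode = "shared")
  set.seed(2)
  K <- 300L
  P_draws <- array(0, c(K, 2, 3, 3))
  for (k in seq_len(K)) {
    Pr <- matrix(rgamma(9, 20), 3); Pr <- Pr / rowSums(Pr)
    jitter1 <- matrix(rgamma(9, 400), 3)
    jitter2 <- matrix(rgamma(9, 400), 3)
    P_draws[k, 1, , ] <- (Pr * jitter1) / rowSums(Pr * jitter1)
    P_draws[k, 2, , ] <- (Pr * jitter2) / rowSums(Pr * jitter2)
  }
  ac <- arm_contrasts(fake_fit_probs(P_draws, spec = spec))
  expect_equal(nrow(ac), 12L)  # 9 transition + 3 stationary contrasts
  expect_true(all(ac$lower <= ac$mean & ac$mean <= ac$upper))
  expect_true(all(!ac$excludes_zero))
})

test_that("arm contrasts detect a constructed diagonal boost", {
  spec <- model_spec(2, M = 2, J = c(1, 1), S = 2, perception_mode = "shared")
  set.seed(3)
  K <- 200L
  P_draws <- array(0, c(K, 2, 2, 2))
  for (k in seq_len(K)) {
    base <- c(0.6, 0.4)
    P_draws[k, 1, 1, ] <- base + rnorm(1, 0, 0.01) * c(1, -1)
    P_draws[k, 1, 2, ] <- c(0.3, 0.7) + rnorm(1, 0, 0.01) * c(1, -1)
    P_draws[k, 2, 1, ] <- c(0.85, 0.15) + rnorm(1, 0, 0.01) * c(1, -1)
    P_draws[k, 2, 2, ] <- c(0.3, 0.7) + rnorm(1, 0, 0.01) * c(1, -1)
  }
  ac <- arm_contrasts(fake_fit_probs(P_draws, spec = spec))
  row <- ac[ac$contrast == "trans[1->1]", ]
  expect_gt(row$mean, 0.2)
  expect_true(row$excludes_zero)
})

test_that("single-draw contrasts degenerate to the point value", {
  spec <- model_spec(2, M = 2, J = c(1, 1), S = 2, perception_mode = "shared")
  P_draws <- array(0, c(1, 2, 2, 2))
  P_draws[1, 1, , ] <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  P_draws[1, 2, , ] <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  ac <- arm_contrasts(fake_fit_probs(P_draws, spec = spec))
  expect_equal(ac$lower, ac$upper)
  expect_equal(ac$mean[ac$contrast == "trans[1->1]"], 0.1)
})

test_that("perception contrasts recover the parent-child diagonal difference", {
  fit <- fixture_fit()
  pc <- perception_contrasts(fit)
  expect_equal(nrow(pc), 9L)
  expect_true(all(pc$lower <= pc$mean & pc$mean <= pc$upper))
  # generating truth: parent diagonals exceed the child's
  # (e.g. Harmonious 0.94 vs 0.75)
  d22 <- pc[pc$contrast == "Q[2->2]", ]
  expect_gt(d22$mean, 0)
  expect_error(perception_contrasts(
    structure(list(spec = model_spec(2, M = 1, J = 1, S = 1,
                                     perception_mode = "shared")),
              class = "phmm_fit")), "two members")
})

test_that("decoding takes the modal state and breaks ties low", {
  spec <- model_spec(2, M = 1, J = 1, S = 1, perception_mode = "shared")
  Z <- array(NA_integer_, c(4, 2, 1))
  Z[, 1, 1] <- c(1L, 1L, 2L, 2L)  # tie -> state 1
  Z[, 2, 1] <- c(2L, 2L, 2L, 1L)
  Zm <- array(Z, c(4, 1, 2, 1))
  fit <- structure(list(draws = list(Z = Z, Zm = Zm), spec = spec,
                        n_draws = 4L,
                        panel_info = list(N = 2L, n = 1L, n_i = c(1L, 1L))),
                   class = "phmm_fit")
  dec <- decode_states(fit)
  expect_equal(dec$Z[, 1], c(1L, 2L))
})

test_that("decoding recovers the truth on well-separated data", {
  preset <- scenario_preset(1, N = 40)
  # shrink noise so states are nearly noiseless
  for (m in 1:2) preset$params$gamma[[m]] <-
    preset$params$gamma[[m]] * 0 + cbind(rep(0.01, 2), 0, 0)
  preset$params$Sigma <- diag(4) * 1e-6
  sim <- simulate_dataset(preset, seed = 4)
  spec <- model_spec(3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "identity")
  cfg <- sampler_config(phase1_iter = 60, phase1_burn = 30,
                        phase2_iter = 120, phase2_burn = 60, thin = 2,
                        seed = 5)
  fit <- run_sampler(sim$panel, spec, cfg)
  dec <- decode_states(fit)
  agree <- mean(align_labels(as.vector(sim$truth$Z), as.vector(dec$Z), 3) ==
                  as.vector(sim$truth$Z))
  expect_gt(agree, 0.97)
})

test_that("identity-model perception approximation behaves structurally", {
  preset <- scenario_preset(1, N = 50)
  sim <- simulate_dataset(preset, seed = 6)
  cfg <- sampler_config(phase1_iter = 60, phase1_burn = 30,
                        phase2_iter = 150, phase2_burn = 70, thin = 2,
                        seed = 7)
  ap <- mhmm_perception_approx(sim$panel, C = 3, config = cfg,
                               mode = "unconstrained")
  for (m in 1:2) {
    expect_equal(unname(rowSums(ap$Q[[m]])), rep(1, 3), tolerance = 1e-12)
    expect_true(all(ap$Q[[m]] >= 0))
    # identity truth: the approximation should be diagonally dominant
    expect_gt(mean(diag(ap$Q[[m]])), 0.5)
  }
  apc <- mhmm_perception_approx(sim$panel, C = 3, config = cfg,
                                mode = "constrained")
  expect_equal(unname(rowSums(apc$Q[[1]])), rep(1, 3), tolerance = 1e-12)
})
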