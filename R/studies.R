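# posterior mean and 95% bounds of the probability blocks of a fit
.fit_probs_summary <- function(fit) {
  d <- fit$draws
  qlo <- function(a, dims) apply(a, dims, stats::quantile, 0.025)
  qhi <- function(a, dims) apply(a, dims, stats::quantile, 0.975)
  list(pi_mean = apply(d$pi, 2:3, mean), pi_lo = qlo(d$pi, 2:3),
       pi_hi = qhi(d$pi, 2:3),
       P_mean = apply(d$P, 2:4, mean), P_lo = qlo(d$P, 2:4),
       P_hi = qhi(d$P, 2:4),
       Q_mean = apply(d$Q, 2:5, mean), Q_lo = qlo(d$Q, 2:5),
       Q_hi = qhi(d$Q, 2:5))
}

# truth blocks in the same array layout as the draws
.truth_blocks <- function(params, fit_spec) {
  spec <- params$spec
  S <- spec$S; C <- spec$C; M <- spec$M
  piT <- params$pi
  PT <- array(0, c(S, C, C))
  for (s in seq_len(S)) PT[s, , ] <- params$P[[s]]
  nq <- if (fit_spec$perception_mode == "arm_specific") S else 1L
  QT <- array(NA_real_, c(M, nq, C, max(spec$C_m)))
  for (m in seq_len(M)) for (s in seq_len(nq)) {
    qt <- if (spec$perception_mode == "arm_specific")
      params$Q[[m]][[min(s, length(params$Q[[m]]))]]
    else params$Q[[m]]
    QT[m, s, , seq_len(spec$C_m[m])] <- qt
  }
  list(pi = piT, P = PT, Q = QT)
}

#' Parameter-recovery study on simulated panels
#'
#' Simulates panels from a scenario preset and fits the requested model to
#' each replicate, recording posterior means, 95% credible bounds and
#' whether each generating probability is covered. Fitting the correctly
#' specified model quantifies recovery; fitting the identity-perception
#' model to perception-generated data quantifies misspecification bias.
#'
#' @param scenario Generating scenario (see [scenario_preset()]).
#' @param model Fitted model: `"phmm"`, `"mhmm"` or `"phmme"`.
#' @param reps Number of simulation replicates.
#' @param config A [sampler_config()] (its seed is re-derived per
#'   replicate).
#' @param seed Base seed.
#' @param N,n Panel dimensions.
#' @return Object of class `phmm_recovery` with per-replicate summaries,
#'   their across-replicate averages (`avg`), entrywise coverage
#'   indicators, and the generating truth.
#' @export
recovery_study <- function(scenario = 2L, model = c("phmm", "mhmm", "phmme"),
                           reps = 5L, config = sampler_config(), seed = 1L,
                           N = 390L, n = 5L) {
  model <- match.arg(model)
  preset <- scenario_preset(scenario, N = N, n = n)
  mode <- switch(model, mhmm = "identity", phmm = "shared",
                 phmme = "arm_specific")
  fit_spec <- model_spec(C = preset$spec$C, M = preset$spec$M,
                         J = preset$spec$J, S = preset$spec$S,
                         q = preset$spec$q, perception_mode = mode)
  per_rep <- vector("list", reps)
  for (rp in seq_len(reps)) {
    sim <- simulate_dataset(preset, seed = seed + 7919L * (rp - 1L))
    cfg <- config
    cfg$seed <- seed + 104729L * rp
    fit <- run_sampler(sim$panel, fit_spec, cfg)
    per_rep[[rp]] <- .fit_probs_summary(fit)
  }
  avg <- per_rep[[1L]]
  if (reps > 1L) for (rp in 2:reps)
    avg <- mapply(`+`, avg, per_rep[[rp]], SIMPLIFY = FALSE)
  avg <- lapply(avg, function(x) x / reps)
  truth <- .truth_blocks(preset$params, fit_spec)
  cover <- function(lo, hi, tr) !is.na(tr) & tr >= lo & tr <= hi
  coverage <- NULL
  if (model != "mhmm" || scenario == 1L) {
    cov_pi <- array(0, dim(truth$pi)); cov_P <- array(0, dim(truth$P))
    cov_Q <- array(0, dim(truth$Q))
    for (rp in seq_len(reps)) {
      s <- per_rep[[rp]]
      cov_pi <- cov_pi + cover(s$pi_lo, s$pi_hi, truth$pi)
      cov_P <- cov_P + cover(s$P_lo, s$P_hi, truth$P)
      if (model != "mhmm" && scenario != 1L &&
          all(dim(s$Q_mean) == dim(truth$Q)))
        cov_Q <- cov_Q + cover(s$Q_lo, s$Q_hi, truth$Q)
    }
    coverage <- list(pi = cov_pi / reps, P = cov_P / reps, Q = cov_Q / reps)
  }
  structure(list(scenario = scenario, model = model, reps = reps,
                 truth = truth, per_rep = per_rep, avg = avg,
                 coverage = coverage),
            class = "phmm_recovery")
}

#' @export
print.phmm_recovery <- function(x, ...) {
  cat(sprintf("recovery study: scenario %d truth, %s fit, %d replicates\n",
              x$scenario, x$model, x$reps))
  cat("average posterior mean initial probabilities (rows = arms):\n")
  print(round(x$avg$pi_mean, 3))
  cat("generating values:\n")
  print(round(x$truth$pi, 3))
  invisible(x)
}

#' WAIC across state counts on perception-generated data
#'
#' Simulates panels from the shared-perception scenario truth and fits the
#' shared-perception model with each requested number of latent states,
#' recording WAIC. On three-state data the drop from two to three states
#' is expected to be much larger than from three to four.
#'
#' @param states Integer vector of state counts to fit.
#' @param reps Number of simulated replicates.
#' @param config A [sampler_config()].
#' @param seed Base seed.
#' @param scenario Generating scenario (default 2, the shared-perception
#'   truth).
#' @param N,n Panel dimensions.
#' @return Matrix `reps x length(states)` of WAIC values (columns named by
#'   state count).
#' @export
waic_study <- function(states = c(2L, 3L, 4L), reps = 3L,
                       config = sampler_config(), seed = 1L,
                       scenario = 2L, N = 390L, n = 5L) {
  preset <- scenario_preset(scenario, N = N, n = n)
  out <- matrix(NA_real_, reps, length(states),
                dimnames = list(NULL, paste0("C", states)))
  for (rp in seq_len(reps)) {
    sim <- simulate_dataset(preset, seed = seed + 7919L * (rp - 1L))
    for (ci in seq_along(states)) {
      Cfit <- states[ci]
      fit_spec <- model_spec(C = Cfit, M = preset$spec$M, J = preset$spec$J,
                             S = preset$spec$S, q = preset$spec$q,
                             perception_mode = "shared")
      cfg <- config
      cfg$seed <- seed + 104729L * rp + 13L * Cfit
      cfg$store_latent <- FALSE
      fit <- run_sampler(sim$panel, fit_spec, cfg)
      out[rp, ci] <- waic(fit)$waic
    }
  }
  out
}
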