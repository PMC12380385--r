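#' Stationary distribution of a transition matrix
#'
#' Left eigenvector at eigenvalue 1, normalized to sum to one, computed by
#' a direct linear solve. Reducible or periodic chains (no unique
#' stationary law) fall back to the limiting Cesaro average from a uniform
#' start, with a warning.
#'
#' @param P Row-stochastic square matrix.
#' @param tol Tolerance for accepting the linear-solve solution.
#' @return Probability vector of length `nrow(P)`.
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  C <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < 0))
    stop("P rows must be probability vectors")
  sol <- tryCatch(
    solve(t(diag(C) - P + matrix(1, C, C)), rep(1, C)),
    error = function(e) NULL)
  if (!is.null(sol) && all(sol > -tol) &&
      max(abs(drop(sol %*% P) - sol)) < tol) {
    sol <- pmax(sol, 0)
    return(sol / sum(sol))
  }
  warning("chain reducible or periodic; returning limiting average from a uniform start")
  Pk <- diag(C)
  acc <- matrix(0, C, C)
  for (k in seq_len(512L)) {
    Pk <- Pk %*% P
    acc <- acc + Pk
  }
  colMeans(acc / 512L)
}

.contrast_df <- function(draw_mat, names) {
  # draw_mat: draws x contrasts
  mean_ <- colMeans(draw_mat)
  lo <- apply(draw_mat, 2L, stats::quantile, 0.025)
  hi <- apply(draw_mat, 2L, stats::quantile, 0.975)
  data.frame(contrast = names, mean = mean_, lower = lo, upper = hi,
             excludes_zero = lo > 0 | hi < 0, row.names = NULL)
}

#' Arm contrasts of transition and stationary probabilities
#'
#' Per posterior draw, the entrywise difference of the two arms' transition
#' matrices and of their stationary distributions is computed and then
#' summarized by the posterior mean and central 95% credible interval
#' (differences are taken draw-by-draw, not between posterior means).
#' Draws whose transition matrix has no unique stationary law are excluded
#' from the stationary contrasts (count reported as an attribute).
#'
#' @param fit A `phmm_fit` with `S = 2` arms (for more arms give `arms`, a
#'   pair of arm indices to contrast).
#' @param arms Length-2 integer vector: contrast `arms[1] - arms[2]`.
#' @return Data frame with columns `contrast`, `mean`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
arm_contrasts <- function(fit, arms = c(2L, 1L)) {
  spec <- fit$spec
  if (spec$S < 2L) stop("arm contrasts need at least two arms")
  C <- spec$C; K <- fit$n_draws
  dP <- matrix(fit$draws$P[, arms[1L], , ] - fit$draws$P[, arms[2L], , ], K, C * C)
  tn <- as.vector(outer(seq_len(C), seq_len(C),
                        function(k, j) sprintf("trans[%d->%d]", k, j)))
  dS <- matrix(NA_real_, K, C)
  dropped <- 0L
  for (k in seq_len(K)) {
    s2 <- tryCatch(suppressWarnings(
      stationary_distribution(matrix(fit$draws$P[k, arms[1L], , ], C, C))),
      error = function(e) NULL)
    s1 <- tryCatch(suppressWarnings(
      stationary_distribution(matrix(fit$draws$P[k, arms[2L], , ], C, C))),
      error = function(e) NULL)
    if (is.null(s1) || is.null(s2)) { dropped <- dropped + 1L; next }
    dS[k, ] <- s2 - s1
  }
  out <- rbind(
    .contrast_df(dP, tn),
    .contrast_df(dS[stats::complete.cases(dS), , drop = FALSE],
                 sprintf("stationary[%d]", seq_len(C))))
  attr(out, "dropped_draws") <- dropped
  out
}

#' Member contrasts of perception probabilities
#'
#' Per draw, the entrywise difference between two members' perception
#' matrices (by default parent minus child), summarized with posterior
#' means and central 95% credible intervals. In identity-perception mode
#' all contrasts are exactly zero (a note attribute records this).
#'
#' @param fit A `phmm_fit` with at least two members.
#' @param members Length-2 vector: contrast `members[1] - members[2]`.
#' @param arm Arm index used in arm-specific mode.
#' @return Data frame as in [arm_contrasts()].
#' @export
perception_contrasts <- function(fit, members = c(2L, 1L), arm = 1L) {
  spec <- fit$spec
  if (spec$M < 2L) stop("perception contrasts need at least two members")
  if (spec$C_m[members[1L]] != spec$C_m[members[2L]])
    stop("members must share a state-space size")
  C <- spec$C; Cm <- spec$C_m[members[1L]]; K <- fit$n_draws
  s_idx <- if (spec$perception_mode == "arm_specific") arm else 1L
  dQ <- matrix(fit$draws$Q[, members[1L], s_idx, , seq_len(Cm)] -
                 fit$draws$Q[, members[2L], s_idx, , seq_len(Cm)], K, C * Cm)
  nm <- as.vector(outer(seq_len(C), seq_len(Cm),
                        function(k, j) sprintf("Q[%d->%d]", k, j)))
  out <- .contrast_df(dQ, nm)
  if (spec$perception_mode == "identity")
    attr(out, "note") <- "identity perception: contrasts are identically zero"
  out
}

#' Posterior-mode decoding of latent states
#'
#' Per cluster-visit, the most frequently sampled state across stored
#' draws; ties broken to the lowest state index.
#'
#' @param fit A `phmm_fit` run with `store_latent = TRUE`.
#' @return List with `Z` (`N x n` modal family states) and `Zm`
#'   (`N x n x M` modal member states); entries beyond a cluster's
#'   follow-up are `NA`.
#' @export
decode_states <- function(fit) {
  if (is.null(fit$draws$Z)) stop("latent draws were not stored")
  spec <- fit$spec
  N <- fit$panel_info$N; n <- fit$panel_info$n
  modal <- function(x, C) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    which.max(tabulate(x, C))
  }
  Z <- matrix(NA_integer_, N, n)
  for (i in seq_len(N)) for (t in seq_len(fit$panel_info$n_i[i]))
    Z[i, t] <- modal(fit$draws$Z[, i, t], spec$C)
  Zm <- array(NA_integer_, c(N, n, spec$M))
  for (m in seq_len(spec$M))
    for (i in seq_len(N)) for (t in seq_len(fit$panel_info$n_i[i]))
      Zm[i, t, m] <- modal(fit$draws$Zm[, m, i, t], spec$C_m[m])
  list(Z = Z, Zm = Zm)
}

#' Approximate perception matrices from identity-perception (MHMM) fits
#'
#' Fits the identity-perception model separately to the full panel (the
#' "family" fit) and to each member's outcomes, decodes the latent states
#' of each fit, aligns every member fit's labels to the family fit by the
#' agreement-maximizing permutation, and row-normalizes the cross-tab of
#' family versus member decoded states. In `"constrained"` mode the member
#' fits are run with emission parameters frozen at the family fit's
#' posterior means.
#'
#' @param panel A `phmm_panel`.
#' @param C Number of latent states.
#' @param config A [sampler_config()] used for each fit.
#' @param mode `"unconstrained"` or `"constrained"`.
#' @return List with `Q` (per-member row-normalized cross-tabs), `counts`,
#'   `mode`, and the decoded state matrices.
#' @export
mhmm_perception_approx <- function(panel, C, config = sampler_config(),
                                   mode = c("unconstrained", "constrained")) {
  mode <- match.arg(mode)
  spec_f <- model_spec(C, M = panel$M, J = panel$J, S = panel$S, q = panel$q,
                       perception_mode = "identity")
  fit_f <- run_sampler(panel, spec_f, config)
  dec_f <- decode_states(fit_f)$Z
  fam_means <- lapply(seq_len(panel$M), function(m) {
    K <- fit_f$n_draws
    tau <- apply(fit_f$draws$tau[, m, seq_len(panel$J[m]), seq_len(C), drop = FALSE],
                 c(3L, 4L), mean)
    gam <- apply(fit_f$draws$gamma[, m, seq_len(panel$J[m]), seq_len(C), drop = FALSE],
                 c(3L, 4L), mean)
    bet <- apply(fit_f$draws$beta[, m, seq_len(panel$J[m]), , drop = FALSE],
                 c(3L, 4L), mean)
    list(tau = matrix(tau, panel$J[m], C), gamma = matrix(gam, panel$J[m], C),
         beta = matrix(bet, panel$J[m], max(panel$q, 1L))[, seq_len(panel$q), drop = FALSE])
  })
  Qhat <- vector("list", panel$M)
  counts <- vector("list", panel$M)
  dec_members <- vector("list", panel$M)
  for (m in seq_len(panel$M)) {
    pm <- .panel_subset_members(panel, m)
    spec_m <- model_spec(C, M = 1L, J = panel$J[m], S = panel$S, q = panel$q,
                         perception_mode = "identity")
    fixed <- if (mode == "constrained")
      list(tau = list(fam_means[[m]]$tau), gamma = list(fam_means[[m]]$gamma),
           beta = list(fam_means[[m]]$beta)) else NULL
    fit_m <- run_sampler(pm, spec_m, config, fixed_emission = fixed)
    dec_m <- decode_states(fit_m)$Z
    ok <- !is.na(dec_f) & !is.na(dec_m)
    aligned <- align_labels(dec_f[ok], dec_m[ok], C)
    dec_al <- dec_m
    perm <- attr(aligned, "perm")
    dec_al[!is.na(dec_al)] <- perm[dec_m[!is.na(dec_m)]]
    ct <- matrix(0, C, C)
    tab <- table(factor(dec_f[ok], levels = seq_len(C)),
                 factor(dec_al[ok], levels = seq_len(C)))
    ct[] <- as.numeric(tab)
    counts[[m]] <- ct
    rs <- rowSums(ct)
    Qhat[[m]] <- ct / ifelse(rs > 0, rs, 1)
    dec_members[[m]] <- dec_al
  }
  list(Q = Qhat, counts = counts, mode = mode, family_states = dec_f,
       member_states = dec_members)
}
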