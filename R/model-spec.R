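#' Define a perception-augmented HMM specification
#'
#' A `phmm_spec` records the dimensions of the three-layer model: a
#' cluster-level Markov chain on `C` states, member-level perceived states
#' (`C_m` states for member `m`), and `J[m]` Gaussian outcomes per member.
#' The perception layer can be the identity (the mixed HMM, "MHMM"), shared
#' across treatment arms ("pHMM"), or arm-specific ("pHMMe").
#'
#' @param C Number of cluster-level latent states.
#' @param M Number of members per cluster (2 for a parent-child dyad).
#' @param J Integer vector of outcomes per member (recycled to length `M`).
#' @param S Number of treatment arms.
#' @param q Number of emission-model covariates.
#' @param perception_mode One of `"shared"`, `"identity"`, `"arm_specific"`.
#' @param C_m Member-level state counts; defaults to `C` for every member.
#'   `perception_mode = "identity"` requires `C_m == C`.
#' @return An object of class `phmm_spec` with fields `C`, `C_m`, `M`, `J`,
#'   `r` (total outcome count), `S`, `q`, `perception_mode`.
#' @export
model_spec <- function(C, M = 2L, J = rep(2L, M), S = 2L, q = 0L,
                       perception_mode = c("shared", "identity", "arm_specific"),
                       C_m = NULL) {
  perception_mode <- match.arg(perception_mode)
  C <- as.integer(C); M <- as.integer(M); S <- as.integer(S); q <- as.integer(q)
  J <- as.integer(rep(J, length.out = M))
  if (C < 1L || M < 1L || S < 1L || q < 0L || any(J < 1L))
    stop("invalid model dimensions: need C >= 1, M >= 1, S >= 1, q >= 0, J >= 1")
  C_m <- if (is.null(C_m)) rep(C, M) else as.integer(rep(C_m, length.out = M))
  if (any(C_m < 1L)) stop("C_m must be >= 1 for every member")
  if (perception_mode == "identity" && any(C_m != C))
    stop("perception_mode = 'identity' forces C_m = C for every member")
  structure(list(C = C, C_m = C_m, M = M, J = J, r = sum(J), S = S, q = q,
                 perception_mode = perception_mode),
            class = "phmm_spec")
}

#' @export
print.phmm_spec <- function(x, ...) {
  cat(sprintf("pHMM specification: C = %d family states, M = %d members (C_m = %s),\n",
              x$C, x$M, paste(x$C_m, collapse = "/")))
  cat(sprintf("  J = %s outcomes/member (r = %d), S = %d arms, q = %d covariates,\n",
              paste(x$J, collapse = "/"), x$r, x$S, x$q))
  cat(sprintf("  perception: %s\n", x$perception_mode))
  invisible(x)
}

#' Construct a parameter set for a perception-augmented HMM
#'
#' Containers follow the model's parameter blocks: arm-specific initial
#' probabilities `pi` and transition matrices `P`, member (optionally arm)
#' specific perception matrices `Q`, cumulative-sum mean increments `tau`
#' and variance increments `gamma` per member and outcome, covariate
#' coefficients `beta`, and the random-effect covariance `Sigma`. State `k`'s
#' emission mean for member `m`, outcome `j` is `sum(tau[[m]][j, 1:k])` and
#' its variance `sum(gamma[[m]][j, 1:k])`.
#'
#' @param spec A [model_spec()].
#' @param pi `S x C` matrix of initial probabilities (rows are arms); a
#'   single vector is recycled across arms.
#' @param P List of `S` row-stochastic `C x C` transition matrices (a single
#'   matrix is recycled).
#' @param Q Perception matrices: for `"shared"` mode a list of `M` matrices
#'   (`C x C_m`); for `"arm_specific"` a list of `M` lists of `S` matrices;
#'   ignored (forced to identity) in `"identity"` mode.
#' @param tau List of `M` matrices `J[m] x C_m[m]` of mean increments.
#' @param beta List of `M` matrices `J[m] x q` of covariate coefficients.
#' @param gamma List of `M` matrices `J[m] x C_m[m]` of variance increments;
#'   cumulative sums must be strictly positive.
#' @param Sigma `r x r` random-effect covariance matrix.
#' @return An object of class `phmm_params`.
#' @export
phmm_params <- function(spec, pi, P, Q = NULL, tau, beta = NULL, gamma,
                        Sigma = diag(spec$r)) {
  stopifnot(inherits(spec, "phmm_spec"))
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = spec$S, ncol = length(pi), byrow = TRUE)
  if (is.matrix(P)) P <- rep(list(P), spec$S)
  if (spec$perception_mode == "identity") {
    Q <- lapply(seq_len(spec$M), function(m) diag(spec$C))
  } else if (is.null(Q)) {
    stop("Q is required unless perception_mode is 'identity'")
  } else if (spec$perception_mode == "arm_specific" && is.matrix(Q[[1L]])) {
    Q <- lapply(Q, function(qm) rep(list(qm), spec$S))
  }
  if (is.null(beta)) beta <- lapply(seq_len(spec$M), function(m)
    matrix(0, spec$J[m], spec$q))
  beta <- lapply(seq_len(spec$M), function(m) {
    bm <- beta[[m]]
    if (is.null(dim(bm))) bm <- matrix(bm, spec$J[m], spec$q)
    bm
  })
  tau <- lapply(tau, as.matrix); gamma <- lapply(gamma, as.matrix)
  obj <- structure(list(pi = pi, P = P, Q = Q, tau = tau, beta = beta,
                        gamma = gamma, Sigma = Sigma, spec = spec),
                   class = "phmm_params")
  .check_param_shapes(obj, spec)
  obj
}

# structural (shape) errors are distinct from invariant violations: the
# former stop(), the latter are reported by validate_params()
.check_param_shapes <- function(params, spec) {
  if (!all(dim(params$pi) == c(spec$S, spec$C)))
    stop("structural error: pi must be S x C")
  if (length(params$P) != spec$S ||
      !all(vapply(params$P, function(p) all(dim(p) == c(spec$C, spec$C)), TRUE)))
    stop("structural error: P must be a list of S C x C matrices")
  for (m in seq_len(spec$M)) {
    qm <- params$Q[[m]]
    qs <- if (spec$perception_mode == "arm_specific") qm else list(qm)
    if (spec$perception_mode == "arm_specific" && length(qs) != spec$S)
      stop("structural error: arm_specific Q needs S matrices per member")
    for (qq in qs)
      if (!all(dim(qq) == c(spec$C, spec$C_m[m])))
        stop(sprintf("structural error: Q[[%d]] must be C x C_m", m))
    for (nm in c("tau", "gamma"))
      if (!all(dim(params[[nm]][[m]]) == c(spec$J[m], spec$C_m[m])))
        stop(sprintf("structural error: %s[[%d]] must be J_m x C_m", nm, m))
    if (!all(dim(params$beta[[m]]) == c(spec$J[m], spec$q)))
      stop(sprintf("structural error: beta[[%d]] must be J_m x q", m))
  }
  if (!all(dim(params$Sigma) == c(spec$r, spec$r)))
    stop("structural error: Sigma must be r x r")
  invisible(TRUE)
}

.simplex_violations <- function(mat, label, tol) {
  out <- character(0)
  for (k in seq_len(nrow(mat))) {
    row <- mat[k, ]
    if (any(row < -tol))
      out <- c(out, sprintf("%s row %d has negative entries", label, k))
    s <- sum(row)
    if (abs(s - 1) > tol)
      out <- c(out, sprintf("%s row %d: row sum %.6g", label, k, s))
  }
  out
}

#' Validate a parameter set against its specification
#'
#' Checks the probabilistic invariants: every row of `pi`, `P` and `Q` is a
#' probability simplex, all cumulative variance sums are strictly positive,
#' and `Sigma` is symmetric positive definite. Shape mismatches are
#' structural errors and stop immediately (see [phmm_params()]).
#'
#' @param params A `phmm_params` object.
#' @param spec A `phmm_spec`; defaults to the one stored in `params`.
#' @param tol Numeric tolerance for simplex sums.
#' @return Character vector of violations; empty if the set is valid.
#' @export
validate_params <- function(params, spec = params$spec, tol = 1e-10) {
  .check_param_shapes(params, spec)
  bad <- .simplex_violations(params$pi, "pi", tol)
  for (s in seq_len(spec$S))
    bad <- c(bad, .simplex_violations(params$P[[s]], sprintf("P[arm %d]", s), tol))
  for (m in seq_len(spec$M)) {
    qs <- if (spec$perception_mode == "arm_specific") params$Q[[m]] else list(params$Q[[m]])
    for (s in seq_along(qs))
      bad <- c(bad, .simplex_violations(qs[[s]], sprintf("Q[member %d%s]", m,
        if (spec$perception_mode == "arm_specific") sprintf(", arm %d", s) else ""), tol))
    if (spec$perception_mode == "identity" &&
        !isTRUE(all.equal(params$Q[[m]], diag(spec$C), tolerance = tol)))
      bad <- c(bad, sprintf("Q[member %d] must be identity in identity mode", m))
    for (j in seq_len(spec$J[m])) {
      vk <- cumsum(params$gamma[[m]][j, ])
      if (any(vk <= 0))
        bad <- c(bad, sprintf("member %d outcome %d: state-%d variance <= 0",
                              m, j, which(vk <= 0)[1L]))
    }
  }
  if (!isSymmetric(unname(params$Sigma), tol = 1e-8)) {
    bad <- c(bad, "Sigma not symmetric")
  } else if (any(eigen(params$Sigma, symmetric = TRUE,
                       only.values = TRUE)$values <= 0)) {
    bad <- c(bad, "Sigma not positive definite")
  }
  bad
}

#' State-wise emission means and variances
#'
#' Converts the cumulative-sum increments of one member/outcome series to
#' per-state moments: `mean_k = sum(tau[1:k])`, `var_k = sum(gamma[1:k])`.
#' Covariate and random-effect contributions are excluded.
#'
#' @param params A `phmm_params` object.
#' @param member Member index.
#' @param outcome Outcome index within the member.
#' @return List with `means` and `variances`, each of length `C_m`.
#' @seealso [to_increments()] for the inverse map.
#' @export
state_moments <- function(params, member, outcome) {
  list(means = cumsum(params$tau[[member]][outcome, ]),
       variances = cumsum(params$gamma[[member]][outcome, ]))
}

#' Convert per-state moments to cumulative-sum increments
#'
#' Inverse of [state_moments()]: returns the first differences. Means may be
#' non-monotone (negative `tau` increments are legitimate); a non-increasing
#' variance sequence yields negative `gamma` increments, which are flagged
#' via the `"nonmonotone_variance"` attribute because they lie outside the
#' support of the inverse-Gamma increments prior (the direct variance
#' sampler accepts them).
#'
#' @param means Numeric vector of per-state means.
#' @param variances Numeric vector of strictly positive per-state variances.
#' @return List with `tau` and `gamma` increment vectors and attribute
#'   `nonmonotone_variance`.
#' @export
to_increments <- function(means, variances) {
  if (length(means) != length(variances))
    stop("means and variances must have equal length")
  if (any(variances <= 0)) stop("variances must be strictly positive")
  out <- list(tau = diff(c(0, means)), gamma = diff(c(0, variances)))
  attr(out, "nonmonotone_variance") <- any(out$gamma < 0)
  out
}

#' Prior configuration for the Gibbs sampler
#'
#' Independent conjugate priors: symmetric Dirichlet on every `pi`/`P`/`Q`
#' row, inverse-Gamma on variance parameters, inverse-Wishart on `Sigma`,
#' and a flat prior on the regression block `(tau, beta)`.
#'
#' @param dirichlet_conc Dirichlet concentration for simplex rows.
#' @param ig_shape,ig_scale Inverse-Gamma shape `a` and scale `b` for the
#'   variance prior (defaults 0.001 and 0.0002).
#' @param iw_df Inverse-Wishart degrees of freedom; defaults to `r + 1` when
#'   resolved against a spec.
#' @param iw_scale Inverse-Wishart scale matrix; defaults to the identity.
#' @return Object of class `phmm_prior`.
#' @export
prior_config <- function(dirichlet_conc = 1, ig_shape = 0.001,
                         ig_scale = 0.0002, iw_df = NULL, iw_scale = NULL) {
  if (dirichlet_conc <= 0 || ig_shape <= 0 || ig_scale <= 0)
    stop("prior hyperparameters must be positive")
  structure(list(dirichlet_conc = dirichlet_conc, ig_shape = ig_shape,
                 ig_scale = ig_scale, iw_df = iw_df, iw_scale = iw_scale),
            class = "phmm_prior")
}

.resolve_prior <- function(prior, spec) {
  if (is.null(prior$iw_df)) prior$iw_df <- spec$r + 1
  if (is.null(prior$iw_scale)) prior$iw_scale <- diag(spec$r)
  if (prior$iw_df < spec$r) stop("inverse-Wishart df must be >= r")
  prior
}

# row-wise cumulative sums / first differences that keep matrix shape for
# single-row and single-column inputs
.row_cumsum <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumsum))
}

.row_decumsum <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, function(x) diff(c(0, x))))
}

# perception matrix for member m in arm s under any mode
.get_Q <- function(params, m, s = 1L) {
  if (params$spec$perception_mode == "arm_specific") params$Q[[m]][[s]]
  else params$Q[[m]]
}

#' Serialize a parameter set to JSON
#'
#' Writes the named blocks `pi`/`P`/`Q`/`tau`/`beta`/`gamma`/`Sigma` and the
#' model dimensions at full precision.
#'
#' @param params A `phmm_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
params_to_json <- function(params, path = NULL) {
  spec <- params$spec
  payload <- list(
    spec = list(C = spec$C, C_m = spec$C_m, M = spec$M, J = spec$J,
                S = spec$S, q = spec$q, perception_mode = spec$perception_mode),
    pi = params$pi, P = params$P, Q = params$Q, tau = params$tau,
    beta = params$beta, gamma = params$gamma, Sigma = params$Sigma)
  js <- jsonlite::toJSON(payload, digits = NA, matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a parameter set from JSON
#'
#' @param path File path or JSON string produced by [params_to_json()].
#' @return A `phmm_params` object.
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  spec <- model_spec(C = x$spec$C, M = x$spec$M, J = x$spec$J, S = x$spec$S,
                     q = x$spec$q, perception_mode = x$spec$perception_mode,
                     C_m = x$spec$C_m)
  as_mats <- function(a) {
    if (is.array(a) && length(dim(a)) == 3L)
      lapply(seq_len(dim(a)[1L]), function(i) a[i, , , drop = TRUE])
    else a
  }
  Q <- x$Q
  if (spec$perception_mode != "arm_specific") {
    Q <- as_mats(Q)
  } else if (is.array(Q) && length(dim(Q)) == 4L) {
    Q <- lapply(seq_len(dim(Q)[1L]), function(m)
      lapply(seq_len(dim(Q)[2L]), function(s) Q[m, s, , ]))
  } else {
    Q <- lapply(Q, as_mats)
  }
  phmm_params(spec, pi = x$pi, P = as_mats(x$P), Q = Q,
              tau = as_mats(x$tau), beta = as_mats(x$beta),
              gamma = as_mats(x$gamma), Sigma = x$Sigma)
}
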