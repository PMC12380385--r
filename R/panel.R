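#' Build a panel object from long-format data
#'
#' The long format has one row per cluster x visit x member x outcome:
#' columns `cluster_id`, `visit`, `arm`, `member`, `outcome`, `value`, plus
#' any cluster-visit covariate columns named in `covariates`. Arm, member
#' and outcome labels are mapped to indices in first-appearance order (the
#' maps are stored on the object). Missing outcome cells (`NA` values, or
#' absent rows) are preserved as missing and simply contribute no emission
#' factor downstream.
#'
#' @param df A data.frame in long format.
#' @param covariates Character vector of covariate column names.
#' @param arm_levels Optional explicit arm level ordering.
#' @param member_levels Optional explicit member level ordering.
#' @return An object of class `phmm_panel` with fields `y` (array
#'   `N x n_max x M x max(J)`), `X` (array `N x n_max x q`), `arm`, `n_i`,
#'   and the label maps.
#' @export
as_panel <- function(df, covariates = character(), arm_levels = NULL,
                     member_levels = NULL) {
  req <- c("cluster_id", "visit", "arm", "member", "outcome", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (length(bad <- setdiff(covariates, names(df))))
    stop("unknown covariate columns: ", paste(bad, collapse = ", "))
  if (!is.numeric(df$value)) stop("column 'value' must be numeric")
  if (any(df$visit %% 1 != 0 | df$visit <= 0))
    stop("visit must be a positive integer; offending rows: ",
         paste(utils::head(which(df$visit %% 1 != 0 | df$visit <= 0), 5), collapse = ", "))
  if (any(!is.na(df$value) & !is.finite(df$value)))
    stop("non-finite outcome values in rows: ",
         paste(utils::head(which(!is.na(df$value) & !is.finite(df$value)), 5), collapse = ", "))

  key <- paste(df$cluster_id, df$visit, df$member, df$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicated (cluster_id, visit, member, outcome) key at row %d: %s/%s/%s/%s",
                 d, df$cluster_id[d], df$visit[d], df$member[d], df$outcome[d]))
  }

  cluster_ids <- unique(df$cluster_id)
  N <- length(cluster_ids)
  ci <- match(df$cluster_id, cluster_ids)
  arm_levels <- if (is.null(arm_levels)) unique(df$arm[order(ci)]) else arm_levels
  member_levels <- if (is.null(member_levels)) unique(df$member) else member_levels
  M <- length(member_levels)
  mi <- match(df$member, member_levels)
  if (anyNA(mi)) stop("member labels outside member_levels")
  outcome_levels <- lapply(seq_len(M), function(m) unique(df$outcome[mi == m]))
  J <- lengths(outcome_levels)

  # arm must be constant within cluster
  arm_by_cluster <- tapply(match(df$arm, arm_levels), ci, function(a) {
    u <- unique(a)
    if (length(u) != 1L) NA_integer_ else u
  })
  if (anyNA(arm_by_cluster))
    stop("arm not constant within cluster(s): ",
         paste(utils::head(cluster_ids[is.na(arm_by_cluster)], 5), collapse = ", "))
  arm <- as.integer(arm_by_cluster[as.character(seq_len(N))])

  # visits mapped to 1..n_i within cluster in increasing order
  visit_tab <- tapply(df$visit, ci, function(v) sort(unique(v)),
                      simplify = FALSE)
  visit_tab <- unname(as.list(visit_tab))
  n_i <- as.integer(lengths(visit_tab))
  n_max <- max(n_i)
  ti <- integer(nrow(df))
  for (i in seq_len(N)) {
    rows <- which(ci == i)
    ti[rows] <- match(df$visit[rows], visit_tab[[i]])
  }

  y <- array(NA_real_, c(N, n_max, M, max(J)))
  ji <- integer(nrow(df))
  for (m in seq_len(M)) {
    rows <- which(mi == m)
    ji[rows] <- match(df$outcome[rows], outcome_levels[[m]])
  }
  y[cbind(ci, ti, mi, ji)] <- df$value

  q <- length(covariates)
  X <- array(NA_real_, c(N, n_max, q))
  if (q > 0) {
    for (k in seq_len(q)) {
      v <- df[[covariates[k]]]
      if (!is.numeric(v)) stop("covariate '", covariates[k], "' must be numeric")
      slab <- X[, , k]
      prev <- slab[cbind(ci, ti)]
      if (any(!is.na(prev) & prev != v))
        stop("covariate '", covariates[k], "' not constant within cluster-visit")
      slab[cbind(ci, ti)] <- v
      X[, , k] <- slab
    }
  }

  structure(list(y = y, X = X, arm = arm, n_i = n_i, N = N, M = M, J = J,
                 S = length(arm_levels), q = q,
                 cluster_ids = cluster_ids, arm_levels = arm_levels,
                 member_levels = member_levels, outcome_levels = outcome_levels,
                 visit_labels = visit_tab, covariates = covariates,
                 transforms = list()),
            class = "phmm_panel")
}

#' @export
print.phmm_panel <- function(x, ...) {
  cat(sprintf("phmm_panel: %d clusters, %d-%d visits, %d members (%s), arms: %s\n",
              x$N, min(x$n_i), max(x$n_i), x$M,
              paste(x$member_levels, collapse = ", "),
              paste(x$arm_levels, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.phmm_panel <- function(x, row.names = NULL, optional = FALSE, ...) {
  g <- expand.grid(i = seq_len(x$N), t = seq_len(max(x$n_i)),
                   m = seq_len(x$M), j = seq_len(max(x$J)),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$t <= x$n_i[g$i] & g$j <= x$J[g$m], , drop = FALSE]
  g <- g[order(g$i, g$t, g$m, g$j), , drop = FALSE]
  out <- data.frame(
    cluster_id = x$cluster_ids[g$i],
    visit = mapply(function(i, t) x$visit_labels[[i]][t], g$i, g$t),
    arm = x$arm_levels[x$arm[g$i]],
    member = x$member_levels[g$m],
    outcome = unlist(x$outcome_levels)[cumsum(c(0L, x$J))[g$m] + g$j],
    value = x$y[cbind(g$i, g$t, g$m, g$j)],
    stringsAsFactors = FALSE)
  if (x$q > 0) for (k in seq_len(x$q))
    out[[x$covariates[k]]] <- x$X[cbind(g$i, g$t, k)]
  rownames(out) <- NULL
  out
}

#' Read a long-format panel CSV
#'
#' @param path CSV file path.
#' @param covariates Covariate column names.
#' @param transforms Named list mapping outcome labels to `"log"` for
#'   outcomes recorded on the natural scale but modeled on the log scale
#'   (applied at read time; recorded on the panel).
#' @param ... Passed to [as_panel()].
#' @return A `phmm_panel`.
#' @export
read_panel <- function(path, covariates = character(), transforms = list(), ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (oc in names(transforms)) {
    if (!identical(transforms[[oc]], "log"))
      stop("unsupported transform: ", transforms[[oc]])
    sel <- df$outcome == oc
    if (any(df$value[sel] <= 0, na.rm = TRUE))
      stop("log transform of non-positive values for outcome ", oc)
    df$value[sel] <- log(df$value[sel])
  }
  p <- as_panel(df, covariates = covariates, ...)
  p$transforms <- transforms
  p
}

#' Write a panel to long-format CSV
#'
#' @param panel A `phmm_panel`.
#' @param path Output CSV path.
#' @param untransform Undo declared log transforms before writing.
#' @export
write_panel <- function(panel, path, untransform = FALSE) {
  df <- as.data.frame(panel)
  if (untransform) for (oc in names(panel$transforms))
    df$value[df$outcome == oc] <- exp(df$value[df$outcome == oc])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a wide-format panel
#'
#' One row per cluster x visit with one column per member-outcome series
#' (e.g. `CDFR`, `CPCC`, `PDFR`, `PPCC` for a dyad).
#'
#' @param df Wide data.frame with `cluster_id`, `visit`, `arm` columns.
#' @param members Named list mapping member label to its outcome columns,
#'   e.g. `list(child = c("CDFR","CPCC"), parent = c("PDFR","PPCC"))`.
#' @param covariates Covariate column names.
#' @return A `phmm_panel`.
#' @export
panel_from_wide <- function(df, members, covariates = character()) {
  long <- list()
  for (m in names(members)) for (oc in members[[m]]) {
    if (!oc %in% names(df)) stop("missing outcome column: ", oc)
    piece <- df[c("cluster_id", "visit", "arm", covariates)]
    piece$member <- m
    piece$outcome <- oc
    piece$value <- df[[oc]]
    long[[length(long) + 1L]] <- piece
  }
  as_panel(do.call(rbind, long), covariates = covariates,
           member_levels = names(members))
}

# restrict a panel to a subset of members (used by the MHMM trio fits)
.panel_subset_members <- function(panel, keep) {
  p <- panel
  p$y <- panel$y[, , keep, , drop = FALSE]
  p$M <- length(keep)
  p$J <- panel$J[keep]
  p$member_levels <- panel$member_levels[keep]
  p$outcome_levels <- panel$outcome_levels[keep]
  p
}

# global outcome index for member m, outcome j
.global_index <- function(J, m, j) if (m == 1L) j else sum(J[seq_len(m - 1L)]) + j
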