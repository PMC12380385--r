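.DRAWS_FORMAT_VERSION <- 1L

#' Write posterior draws to disk
#'
#' Serializes a `phmm_fit` (draw arrays, metadata, seeds, pointwise
#' log-likelihoods) with a format version so a mismatched file is refused
#' on read rather than silently misread.
#'
#' @param fit A `phmm_fit`.
#' @param path Output file path.
#' @export
write_draws <- function(fit, path) {
  if (!inherits(fit, "phmm_fit")) stop("fit must be a phmm_fit")
  if (is.null(fit$n_draws) || fit$n_draws < 1L) stop("fit holds no draws")
  saveRDS(list(format = "phmm_draws", version = .DRAWS_FORMAT_VERSION,
               fit = fit), path)
  invisible(path)
}

#' Read posterior draws from disk
#'
#' @param path File written by [write_draws()].
#' @return The stored `phmm_fit`.
#' @export
read_draws <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "phmm_draws"))
    stop("not a phmm draws file")
  if (!identical(x$version, .DRAWS_FORMAT_VERSION))
    stop(sprintf("draws file version %s does not match supported version %d",
                 x$version, .DRAWS_FORMAT_VERSION))
  x$fit
}
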