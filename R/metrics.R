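#' One-vs-rest confusion counts for multi-class state calling
#'
#' For each class `z`, an item counts as a true positive if both truth and
#' prediction equal `z`, a false positive if only the prediction does, a
#' false negative if only the truth does, and a true negative otherwise;
#' every class's four counts sum to the number of items.
#'
#' @param truth,predicted Integer label vectors (equal length, values in
#'   `1..C`).
#' @param C Number of classes.
#' @return Object of class `phmm_confusion`: `C x 4` matrix with columns
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, C) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  lab <- c(truth, predicted)
  if (any(is.na(lab)) || any(lab < 1L | lab > C) || any(lab %% 1 != 0))
    stop("labels must be integers in 1..", C)
  n <- length(truth)
  out <- matrix(0L, C, 4L, dimnames = list(paste0("class", seq_len(C)),
                                           c("tp", "tn", "fp", "fn")))
  for (z in seq_len(C)) {
    tp <- sum(truth == z & predicted == z)
    fp <- sum(truth != z & predicted == z)
    fn <- sum(truth == z & predicted != z)
    out[z, ] <- c(tp, n - tp - fp - fn, fp, fn)
  }
  class(out) <- c("phmm_confusion", class(out))
  out
}

#' Six multi-class state-calling criteria
#'
#' Macro-averaged accuracy, error rate, precision, recall; micro-precision
#' (pooled counts; equal to micro-recall and micro-F here since every item
#' gets exactly one label); and the F-score computed as
#' `Precision * Recall / (Precision + Recall)` — the reported convention,
#' which is half the usual harmonic mean (so perfect calling yields 0.5).
#' `f_score = "conventional"` restores the factor 2. Per-class terms with
#' zero denominator are set to 0 with a warning.
#'
#' @param ct A [confusion_counts()] table.
#' @param f_score `"printed"` (default) or `"conventional"`.
#' @return Named numeric vector: `accuracy`, `error_rate`,
#'   `micro_precision`, `precision`, `recall`, `f_score`.
#' @export
classification_metrics <- function(ct, f_score = c("printed", "conventional")) {
  f_score <- match.arg(f_score)
  C <- nrow(ct)
  tp <- ct[, "tp"]; tn <- ct[, "tn"]; fp <- ct[, "fp"]; fn <- ct[, "fn"]
  tot <- tp + tn + fp + fn
  if (any(tot <= 0)) stop("empty confusion table")
  safe <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) warning("zero denominator in per-class ", what,
                          "; affected terms set to 0")
    out <- ifelse(bad, 0, num / ifelse(bad, 1, den))
    out
  }
  accuracy <- mean((tp + tn) / tot)
  error_rate <- mean((fp + fn) / tot)
  micro_precision <- sum(tp) / sum(tp + fp)
  precision <- mean(safe(tp, tp + fp, "precision"))
  recall <- mean(safe(tp, tp + fn, "recall"))
  fs <- if (precision + recall == 0) 0
    else precision * recall / (precision + recall)
  if (f_score == "conventional") fs <- 2 * fs
  c(accuracy = accuracy, error_rate = error_rate,
    micro_precision = micro_precision, precision = precision,
    recall = recall, f_score = fs)
}

#' Align predicted latent-state labels to the truth
#'
#' Latent labels are arbitrary; before computing calling metrics the
#' predicted labels are permuted to maximize agreement with the truth
#' (exhaustive search over the `C!` permutations).
#'
#' @param truth,predicted Integer label vectors in `1..C`.
#' @param C Number of classes.
#' @return Relabeled prediction vector with attribute `"perm"` (the map
#'   old label -> new label).
#' @export
align_labels <- function(truth, predicted, C) {
  perms <- .perms(C)
  best <- NULL; best_score <- -1L
  for (p in perms) {
    sc <- sum(truth == p[predicted])
    if (sc > best_score) { best_score <- sc; best <- p }
  }
  out <- best[predicted]
  attr(out, "perm") <- best
  out
}
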