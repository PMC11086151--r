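#' Confusion matrix with ES as the positive class
#'
#' @param labels,predictions Equal-length vectors of `"ES"` / `"PNES"`.
#' @return An object of class `confusion_matrix` with integer counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) == 0L) stop("empty input")
  if (!all(c(labels, predictions) %in% c("ES", "PNES")))
    stop("labels must be 'ES' or 'PNES'")
  confusion_matrix(tp = sum(labels == "ES" & predictions == "ES"),
                   fp = sum(labels == "PNES" & predictions == "ES"),
                   fn = sum(labels == "ES" & predictions == "PNES"),
                   tn = sum(labels == "PNES" & predictions == "PNES"))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative counts (true/false positives/negatives).
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("ES", "PNES"),
                              actual = c("ES", "PNES")))
  print(m)
  invisible(x)
}

#' Pool confusion matrices across test sites
#'
#' Element-wise sum of counts; this is the image-pooling convention for
#' combined multi-site metrics.
#'
#' @param cms Non-empty list of `confusion_matrix` objects.
#' @return A `confusion_matrix`.
#' @export
pool_confusions <- function(cms) {
  if (length(cms) == 0L) stop("need at least one confusion matrix")
  stopifnot(all(vapply(cms, inherits, logical(1), "confusion_matrix")))
  confusion_matrix(tp = sum(vapply(cms, `[[`, integer(1), "tp")),
                   fp = sum(vapply(cms, `[[`, integer(1), "fp")),
                   fn = sum(vapply(cms, `[[`, integer(1), "fn")),
                   tn = sum(vapply(cms, `[[`, integer(1), "tn")))
}

#' Wilson score interval for a binomial proportion
#'
#' Confidence interval obtained by inverting the score test; unlike the
#' Wald interval it stays inside `[0, 1]` and behaves well near 0 and 1,
#' which matters for specificities close to 100%.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `> 0`.
#' @param confidence Coverage level (default 0.95; z is the exact normal
#'   quantile, 1.959964 at 95%).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Diagnostic metrics with Wilson confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy of a 2x2 confusion matrix (ES positive), each with a Wilson
#' score interval computed from that metric's own numerator and
#' denominator. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param confidence Interval coverage level.
#' @return data.frame with columns `metric`, `estimate`, `lo`, `hi`, `k`,
#'   `n`; class `metric_set`.
#' @export
seizure_metrics <- function(cm, confidence = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0L) stop("confusion matrix is empty")
  defs <- list(sensitivity = c(cm$tp, cm$tp + cm$fn),
               specificity = c(cm$tn, cm$tn + cm$fp),
               ppv = c(cm$tp, cm$tp + cm$fp),
               npv = c(cm$tn, cm$tn + cm$fn),
               accuracy = c(cm$tp + cm$tn, total))
  rows <- lapply(names(defs), function(m) {
    k <- defs[[m]][1]
    n <- defs[[m]][2]
    if (n == 0) {
      data.frame(metric = m, estimate = NA_real_, lo = NA_real_,
                 hi = NA_real_, k = k, n = n)
    } else {
      ci <- wilson_interval(k, n, confidence)
      data.frame(metric = m, estimate = k / n, lo = ci[["lo"]],
                 hi = ci[["hi"]], k = k, n = n)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metric
  class(out) <- c("metric_set", "data.frame")
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat("Measure       Estimate (95% CI)\n")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("%-12s  undefined (n = 0)\n", x$metric[i]))
    } else {
      cat(sprintf("%-12s  %.1f%% [%.1f%% to %.1f%%]\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$lo[i], 100 * x$hi[i]))
    }
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the ES-probability scores and
#' integrates the curve by the trapezoidal rule. With proper handling of
#' tied scores this equals the Mann-Whitney probability estimator: the
#' proportion of (ES, PNES) pairs in which the ES image scores higher,
#' ties counted one half.
#'
#' @param scores Numeric vector of ES scores (higher = more ES-like).
#' @param labels `"ES"` / `"PNES"` per score; both classes must be
#'   present.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == "ES")
  nneg <- sum(labels == "PNES")
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord] == "ES"
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- tapply(y, grp, sum)
  fp <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp) / npos)
  fpr <- c(0, cumsum(fp) / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  curve <- data.frame(threshold = c(Inf, s[!duplicated(grp)]),
                      fpr = fpr, tpr = tpr)
  list(curve = curve, auc = auc)
}
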