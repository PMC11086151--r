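#' Published two-site evaluation counts
#'
#' Confusion matrices reported by the two-site clinical evaluation of EEG
#' plot-image seizure classification that this package models (Site A:
#' 396 test images, 138 ES / 258 PNES; Site B, a different centre and
#' review software: 1365 test images, 408 ES / 957 PNES). Every published
#' site-level metric — accuracy, sensitivity, specificity, PPV, NPV, and
#' their Wilson intervals, individually and pooled — is a deterministic
#' function of these counts, so they anchor the evaluation stage against
#' known values.
#'
#' @return Named list with `confusion_matrix` elements `site_a` and
#'   `site_b`.
#' @export
#' @examples
#' seizure_metrics(site_confusions()$site_a)
site_confusions <- function() {
  list(site_a = confusion_matrix(tp = 90, fp = 4, fn = 48, tn = 254),
       site_b = confusion_matrix(tp = 390, fp = 155, fn = 18, tn = 802))
}
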