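#' Band-pass filter specification
#'
#' Clinical display filter: 0.3 Hz low cut and 70 Hz high cut. Implemented
#' as a Butterworth band-pass of the given order applied forward-backward
#' (zero phase), so waveform morphology is preserved for rendering. Each
#' channel is demeaned before filtering, which removes DC exactly and keeps
#' the filter's edge transients negligible.
#'
#' @param low_cut Low cut-off, Hz.
#' @param high_cut High cut-off, Hz; must stay below the Nyquist frequency.
#' @param order Butterworth design order (per band edge).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.3, high_cut = 70, order = 4) {
  if (!(low_cut > 0 && low_cut < high_cut)) stop("need 0 < low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order),
            class = "filter_spec")
}

#' Apply the clinical band-pass filter
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return A filtered [eeg_recording()] of identical dimensions.
#' @export
apply_bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$high_cut >= rec$fs / 2)
    stop("high_cut (", spec$high_cut, " Hz) must be below Nyquist (",
         rec$fs / 2, " Hz)")
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (rec$fs / 2),
                       type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    out$data[i, ] <- signal::filtfilt(bf, x - mean(x))
  }
  out
}

#' Montage specification
#'
#' An ordered list of display derivations. Each derivation is the trace of
#' a positive electrode minus that of a negative electrode, or minus the
#' common average (`"AVG"`) of the 19 standard 10-20 scalp electrodes
#' (FT9/FT10 are excluded from the average).
#'
#' @param name Montage name.
#' @param derivations data.frame with columns `label`, `pos`, `neg`
#'   (electrode labels; `neg` may be `"AVG"`).
#' @param avg_channels Electrodes entering the common average.
#' @return An object of class `montage_spec`.
#' @export
montage_spec <- function(name, derivations,
                         avg_channels = scalp_1020_channels()) {
  stopifnot(all(c("label", "pos", "neg") %in% names(derivations)))
  if (anyDuplicated(derivations$label)) stop("derivation labels must be unique")
  els <- c(derivations$pos, setdiff(derivations$neg, "AVG"), avg_channels)
  bad <- setdiff(els, eeg_channels())
  if (length(bad)) stop("unknown electrode(s): ", paste(bad, collapse = ", "))
  structure(list(name = name,
                 derivations = as.data.frame(derivations,
                                             stringsAsFactors = FALSE),
                 avg_channels = avg_channels),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> %s: %d derivations\n", x$name,
              nrow(x$derivations)))
  invisible(x)
}

chain <- function(...) {
  e <- c(...)
  data.frame(label = paste0(e[-length(e)], "-", e[-1]),
             pos = e[-length(e)], neg = e[-1], stringsAsFactors = FALSE)
}

#' Built-in clinical display montages
#'
#' The four montages used for display and training diversity:
#' \describe{
#'   \item{ap_bipolar}{Longitudinal anterior-posterior bipolar ("double
#'     banana"), 18 derivations: left and right temporal chains
#'     (Fp1-F7-T3-T5-O1, Fp2-F8-T4-T6-O2), left and right parasagittal
#'     chains (Fp1-F3-C3-P3-O1, Fp2-F4-C4-P4-O2), midline Fz-Cz-Pz.}
#'   \item{average_referential}{Each of the 19 standard 10-20 scalp
#'     electrodes against the common average of those 19.}
#'   \item{transverse_bipolar}{Standard transverse chains across the
#'     frontal, central, parietal and occipital rows, 18 derivations.}
#'   \item{phase1}{A longitudinal/transverse montage centred on the
#'     inferior temporal electrodes FT9/FT10: inferior temporal chains
#'     Fp1-F7-FT9-T3-T5-O1 and Fp2-F8-FT10-T4-T6-O2 plus a transverse
#'     chain FT9-Cz-FT10, 12 derivations. The exact list is a fixed
#'     convention of this package; it contributes training-set diversity
#'     only (evaluation uses ap_bipolar).}
#' }
#'
#' @return Named list of four [montage_spec()] objects.
#' @export
builtin_montages <- function() {
  ap <- rbind(chain("Fp1", "F7", "T3", "T5", "O1"),
              chain("Fp2", "F8", "T4", "T6", "O2"),
              chain("Fp1", "F3", "C3", "P3", "O1"),
              chain("Fp2", "F4", "C4", "P4", "O2"),
              chain("Fz", "Cz", "Pz"))
  avg <- data.frame(label = paste0(scalp_1020_channels(), "-AVG"),
                    pos = scalp_1020_channels(), neg = "AVG",
                    stringsAsFactors = FALSE)
  tv <- rbind(chain("F7", "Fp1", "Fp2", "F8"),
              chain("F7", "F3", "Fz", "F4", "F8"),
              chain("T3", "C3", "Cz", "C4", "T4"),
              chain("T5", "P3", "Pz", "P4", "T6"),
              chain("T5", "O1", "O2", "T6"))
  p1 <- rbind(chain("Fp1", "F7", "FT9", "T3", "T5", "O1"),
              chain("Fp2", "F8", "FT10", "T4", "T6", "O2"),
              chain("FT9", "Cz", "FT10"))
  list(ap_bipolar = montage_spec("ap_bipolar", ap),
       average_referential = montage_spec("average_referential", avg),
       transverse_bipolar = montage_spec("transverse_bipolar", tv),
       phase1 = montage_spec("phase1", p1))
}

#' Derive a display montage from a referential recording
#'
#' @param rec An [eeg_recording()] containing every electrode the montage
#'   references.
#' @param spec A [montage_spec()].
#' @return An object of class `derived_recording` with fields `data`
#'   (derivation x sample matrix, microvolts, row names = derivation
#'   labels), `montage`, `fs`, `subject_id`, `event_id`.
#' @export
derive_montage <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "montage_spec"))
  need <- unique(c(spec$derivations$pos,
                   setdiff(spec$derivations$neg, "AVG"),
                   if (any(spec$derivations$neg == "AVG")) spec$avg_channels))
  missing <- setdiff(need, rec$channels)
  if (length(missing))
    stop("recording lacks electrode(s): ", paste(missing, collapse = ", "))
  avg <- if (any(spec$derivations$neg == "AVG"))
    colMeans(rec$data[spec$avg_channels, , drop = FALSE]) else NULL
  d <- spec$derivations
  m <- matrix(0, nrow(d), ncol(rec$data),
              dimnames = list(d$label, NULL))
  for (i in seq_len(nrow(d))) {
    neg <- if (d$neg[i] == "AVG") avg else rec$data[d$neg[i], ]
    m[i, ] <- rec$data[d$pos[i], ] - neg
  }
  structure(list(data = m, montage = spec, fs = rec$fs,
                 subject_id = rec$subject_id, event_id = rec$event_id),
            class = "derived_recording")
}

#' @export
print.derived_recording <- function(x, ...) {
  cat(sprintf("<derived_recording> %s/%s: montage %s, %d derivations x %d samples @ %g Hz\n",
              x$subject_id, x$event_id, x$montage$name, nrow(x$data),
              ncol(x$data), x$fs))
  invisible(x)
}
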