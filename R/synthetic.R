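#' Synthetic EEG generator configuration
#'
#' Parameters of the seeded synthetic EEG cohort generator. The generator
#' emulates the three signal regimes the downstream image pipeline must
#' discriminate: interictal background (band-limited alpha rhythm over
#' 1/f-shaped noise), evolving rhythmic ictal discharges (frequency sweep
#' with an amplitude ramp), and broadband movement/EMG artifact bursts.
#'
#' Amplitudes are in microvolts so that rendered deflections obey the
#' 1 pixel-per-microvolt display calibration downstream.
#'
#' @param fs Sampling rate, Hz (250 or 1000 in the emulated clinics).
#' @param duration_s Recording length per event, seconds.
#' @param alpha_amp_uv Posterior-dominant alpha rhythm amplitude, microvolts.
#' @param alpha_band Alpha band (low, high), Hz; per-channel carrier
#'   frequencies are drawn inside it.
#' @param noise_amp_uv RMS of the 1/f-shaped background noise, microvolts.
#' @param ictal_freq_start_hz,ictal_freq_end_hz Frequency sweep of the
#'   rhythmic ictal discharge (seizures typically slow as they evolve).
#' @param ictal_amp_uv Peak amplitude the ictal ramp reaches, microvolts.
#' @param artifact_amp_uv RMS of movement-artifact bursts inside artifact
#'   intervals, microvolts. Bursts mix broadband EMG with the 60 Hz mains
#'   pickup that accompanies electrode movement.
#' @param artifact_band Band of the generated EMG component, Hz. Muscle
#'   activity is broadband; generation extends above the clinical 70 Hz
#'   high cut so that after display filtering the visible energy fills
#'   20-70 Hz densely.
#' @param sway_amp_uv Amplitude of the low-frequency movement sway added
#'   with artifact bursts, microvolts.
#' @param channel_weights Named vector of per-channel ictal weights in
#'   `[0, 1]`; default emphasises the temporal chain, where clinical ictal
#'   rhythms are most often maximal.
#' @param pnes_artifact_prob Probability that a synthetic PNES event carries
#'   movement artifact bursts (clinically, abnormal movements contaminate
#'   many but not all PNES recordings).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(fs = 250, duration_s = 60,
                             alpha_amp_uv = 10, alpha_band = c(8, 12),
                             noise_amp_uv = 5,
                             ictal_freq_start_hz = 5, ictal_freq_end_hz = 2.5,
                             ictal_amp_uv = 100,
                             artifact_amp_uv = 300, artifact_band = c(35, 110),
                             sway_amp_uv = 50,
                             channel_weights = default_ictal_weights(),
                             pnes_artifact_prob = 0.5,
                             seed = 1L) {
  amps <- c(alpha_amp_uv, noise_amp_uv, ictal_amp_uv, artifact_amp_uv, sway_amp_uv)
  if (!all(is.finite(amps)) || any(amps < 0))
    stop("amplitudes must be finite and >= 0")
  freqs <- c(alpha_band, ictal_freq_start_hz, ictal_freq_end_hz, artifact_band)
  if (any(freqs >= fs / 2)) stop("all frequencies must be below fs/2")
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be > 0")
  structure(
    list(fs = fs, duration_s = duration_s,
         alpha_amp_uv = alpha_amp_uv, alpha_band = alpha_band,
         noise_amp_uv = noise_amp_uv,
         ictal_freq_start_hz = ictal_freq_start_hz,
         ictal_freq_end_hz = ictal_freq_end_hz,
         ictal_amp_uv = ictal_amp_uv,
         artifact_amp_uv = artifact_amp_uv, artifact_band = artifact_band,
         sway_amp_uv = sway_amp_uv,
         channel_weights = channel_weights,
         pnes_artifact_prob = pnes_artifact_prob,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' @rdname generator_config
#' @details `default_ictal_weights()` gives temporal-chain channels full
#'   weight, frontal channels 0.7, and the remaining electrodes 0.4.
#' @export
default_ictal_weights <- function() {
  ch <- eeg_channels()
  w <- stats::setNames(rep(0.4, length(ch)), ch)
  w[c("F7", "F8", "T3", "T4", "T5", "T6", "FT9", "FT10")] <- 1
  w[c("Fp1", "Fp2", "F3", "F4")] <- 0.7
  w
}

# 1/f-shaped noise of length n, unit RMS, via spectral shaping of white
# noise (power ~ 1/f above 1 Hz, flat below to keep variance finite).
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- seq(0, fs, length.out = n + 1)[1:n]
  freq <- pmin(freq, fs - freq)          # two-sided frequency axis
  shape <- 1 / sqrt(pmax(freq, 1))
  shape[1] <- 0                          # no DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate interictal background EEG
#'
#' Produces a referential recording in which every channel is a mixture of
#' a band-limited alpha oscillation (slowly amplitude-modulated, with a
#' per-channel carrier frequency drawn inside `alpha_band`) and 1/f-shaped
#' noise, at the configured microvolt amplitudes.
#'
#' @param config A [generator_config()].
#' @param subject_id,event_id Identifiers for the produced recording.
#' @return An [eeg_recording()].
#' @export
generate_background <- function(config, subject_id = "S0", event_id = "E0") {
  stopifnot(inherits(config, "generator_config"))
  ch <- eeg_channels()
  n <- round(config$fs * config$duration_s)
  t <- (seq_len(n) - 1) / config$fs
  seed <- event_seed(config$seed, paste0("bg:", event_id))
  data <- with_seed(seed, {
    m <- matrix(0, length(ch), n)
    for (i in seq_along(ch)) {
      f <- stats::runif(1, config$alpha_band[1], config$alpha_band[2])
      phase <- stats::runif(1, 0, 2 * pi)
      # slow (~0.3 Hz) amplitude modulation of the alpha rhythm
      env <- 1 + 0.3 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
      alpha <- config$alpha_amp_uv * env * sin(2 * pi * f * t + phase)
      noise <- if (config$noise_amp_uv > 0)
        config$noise_amp_uv * pink_noise(n, config$fs) else 0
      m[i, ] <- alpha + noise
    }
    m
  })
  eeg_recording(data, config$fs, ch, subject_id, event_id)
}

#' Inject a rhythmic ictal discharge
#'
#' Adds an evolving rhythmic discharge to a recording inside a half-open
#' time interval: the instantaneous frequency sweeps linearly from
#' `ictal_freq_start_hz` to `ictal_freq_end_hz` while the amplitude ramps
#' up to `ictal_amp_uv`, distributed over channels according to
#' `channel_weights`. The annotation gains the interval and event type ES.
#'
#' @param rec An [eeg_recording()].
#' @param interval `(start_s, end_s)` in seconds, inside the recording.
#' @param config A [generator_config()].
#' @param annotation Optional existing [event_annotation()] to extend;
#'   injecting an interval overlapping an existing ictal interval is an
#'   error.
#' @return List with elements `recording` and `annotation`.
#' @export
inject_ictal <- function(rec, interval, config, annotation = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  interval <- as.numeric(interval)
  dur <- recording_duration(rec)
  if (interval[1] < 0 || interval[2] > dur || interval[1] >= interval[2])
    stop("ictal interval must lie inside the recording")
  if (!is.null(annotation) &&
      interval_overlap_s(interval[1], interval[2], annotation$ictal_intervals) > 0)
    stop("interval overlaps an existing ictal interval")

  i0 <- floor(interval[1] * rec$fs) + 1L
  i1 <- floor(interval[2] * rec$fs)
  n <- i1 - i0 + 1L
  seed <- event_seed(config$seed, paste0("ictal:", rec$event_id))
  burst <- with_seed(seed, {
    u <- (seq_len(n) - 1) / max(n - 1, 1)
    f <- config$ictal_freq_start_hz +
      u * (config$ictal_freq_end_hz - config$ictal_freq_start_hz)
    phase <- 2 * pi * cumsum(f) / rec$fs + stats::runif(1, 0, 2 * pi)
    ramp <- 0.25 + 0.75 * u            # discharge builds as it evolves
    # half-second cosine taper at both ends avoids step discontinuities
    taper <- rep(1, n)
    k <- min(n, round(0.5 * rec$fs))
    taper[seq_len(k)] <- (1 - cos(pi * seq_len(k) / k)) / 2
    taper[n + 1 - seq_len(k)] <- pmin(taper[n + 1 - seq_len(k)],
                                      (1 - cos(pi * seq_len(k) / k)) / 2)
    config$ictal_amp_uv * ramp * taper * sin(phase)
  })
  w <- config$channel_weights[rec$channels]
  w[is.na(w)] <- 0
  rec$data[, i0:i1] <- rec$data[, i0:i1] + outer(as.numeric(w), burst)

  ictal <- rbind(if (!is.null(annotation)) annotation$ictal_intervals,
                 matrix(interval, ncol = 2))
  ann <- event_annotation("ES", ictal_intervals = ictal,
                          artifact_intervals =
                            if (!is.null(annotation)) annotation$artifact_intervals,
                          duration_s = dur)
  list(recording = rec, annotation = ann)
}

#' Inject a movement/EMG artifact burst
#'
#' Adds broadband high-frequency muscle-activity noise (band-limited to
#' `artifact_band`, spectrally tilted upward as surface EMG is), 60 Hz
#' mains pickup from electrode movement, and a low-frequency movement sway
#' inside a half-open interval, on all channels. After the clinical
#' 0.3-70 Hz display filter the visible burst energy lies at 20-70 Hz.
#' The annotation records the interval under
#' `artifact_intervals`; the event type is left unchanged (artifact occurs
#' in both ES and PNES recordings).
#'
#' @inheritParams inject_ictal
#' @param amp_uv RMS amplitude of the burst; defaults to
#'   `config$artifact_amp_uv`.
#' @return List with elements `recording` and `annotation`.
#' @export
inject_movement_artifact <- function(rec, interval, config, annotation = NULL,
                                     amp_uv = config$artifact_amp_uv) {
  stopifnot(inherits(rec, "eeg_recording"))
  interval <- as.numeric(interval)
  dur <- recording_duration(rec)
  if (interval[1] < 0 || interval[2] > dur || interval[1] >= interval[2])
    stop("artifact interval must lie inside the recording")

  i0 <- floor(interval[1] * rec$fs) + 1L
  i1 <- floor(interval[2] * rec$fs)
  n <- i1 - i0 + 1L
  nch <- nrow(rec$data)
  seed <- event_seed(config$seed,
                     paste0("emg:", rec$event_id, ":", interval[1]))
  if (amp_uv > 0) {
    add <- with_seed(seed, {
      bf <- signal::butter(4, config$artifact_band / (rec$fs / 2), type = "pass")
      m <- matrix(0, nch, n)
      sway_f <- stats::runif(1, 0.3, 1)
      tt <- (seq_len(n) - 1) / rec$fs
      for (i in seq_len(nch)) {
        # band-limit, then first-difference: surface EMG has a rising
        # (+6 dB/octave) spectrum peaking well above the EEG bands
        emg <- diff(c(0, as.numeric(signal::filter(bf, stats::rnorm(n)))))
        s <- stats::sd(emg)
        if (s > 0) emg <- emg / s
        # electrode movement also picks up mains interference (60 Hz)
        mains <- sqrt(2) * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
        sway <- sin(2 * pi * sway_f * tt + stats::runif(1, 0, 2 * pi))
        m[i, ] <- amp_uv * (emg + 2 * mains) / sqrt(5) +
          config$sway_amp_uv * sway
      }
      m
    })
    rec$data[, i0:i1] <- rec$data[, i0:i1] + add
  }
  art <- rbind(if (!is.null(annotation)) annotation$artifact_intervals,
               matrix(interval, ncol = 2))
  type <- if (!is.null(annotation)) annotation$event_type else "PNES"
  ann <- event_annotation(type,
                          ictal_intervals =
                            if (!is.null(annotation)) annotation$ictal_intervals,
                          artifact_intervals = art, duration_s = dur)
  list(recording = rec, annotation = ann)
}

#' Generate a synthetic two-class cohort
#'
#' Builds `n_es` epileptic-seizure events (background plus one rhythmic
#' ictal discharge at a randomized interval) and `n_pnes` psychogenic
#' non-epileptic events (background, with movement artifact bursts at the
#' configured prevalence). Subject and event identifiers are distinct;
#' each synthetic subject contributes up to two events of a single class,
#' mirroring the one-diagnosis-per-subject structure of clinical cohorts.
#' Per-event RNG substreams make the cohort a pure function of
#' (config, seed).
#'
#' @param config A [generator_config()].
#' @param n_es,n_pnes Non-negative event counts.
#' @return List of `list(recording, annotation)` pairs, ES events first.
#' @export
generate_cohort <- function(config, n_es, n_pnes) {
  stopifnot(inherits(config, "generator_config"), n_es >= 0, n_pnes >= 0)
  out <- vector("list", n_es + n_pnes)
  dur <- config$duration_s
  for (i in seq_len(n_es)) {
    ev <- sprintf("ES%03d", i)
    sub <- sprintf("subE%03d", ceiling(i / 2))
    rec <- generate_background(config, sub, ev)
    iv <- with_seed(event_seed(config$seed, paste0("plan:", ev)), {
      len <- stats::runif(1, min(25, dur * 0.5), min(35, dur * 0.6))
      start <- stats::runif(1, dur * 0.15, dur - len - 1)
      c(start, start + len)
    })
    out[[i]] <- inject_ictal(rec, iv, config)
  }
  for (j in seq_len(n_pnes)) {
    ev <- sprintf("PNES%03d", j)
    sub <- sprintf("subP%03d", ceiling(j / 2))
    rec <- generate_background(config, sub, ev)
    ann <- event_annotation("PNES", duration_s = dur)
    plan <- with_seed(event_seed(config$seed, paste0("plan:", ev)), {
      if (stats::runif(1) < config$pnes_artifact_prob) {
        k <- sample(1:2, 1)
        starts <- sort(stats::runif(k, 2, dur - 8))
        lens <- stats::runif(k, 3, 6)
        amps <- config$artifact_amp_uv * stats::runif(k, 0.3, 1)
        list(starts = starts, lens = lens, amps = amps)
      } else NULL
    })
    if (!is.null(plan)) {
      for (b in seq_along(plan$starts)) {
        r <- inject_movement_artifact(
          rec, c(plan$starts[b], min(plan$starts[b] + plan$lens[b], dur)),
          config, ann, amp_uv = plan$amps[b])
        rec <- r$recording
        ann <- r$annotation
      }
    }
    out[[n_es + j]] <- list(recording = rec, annotation = ann)
  }
  out
}

#' Cohort manifest
#'
#' Summarises a generated cohort as a data frame suitable for writing to
#' CSV: one row per event with subject, event, class and interval counts.
#'
#' @param cohort Output of [generate_cohort()].
#' @return A data.frame with columns `subject_id`, `event_id`,
#'   `event_type`, `duration_s`, `n_ictal`, `n_artifact`.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(ev) {
    data.frame(subject_id = ev$recording$subject_id,
               event_id = ev$recording$event_id,
               event_type = ev$annotation$event_type,
               duration_s = recording_duration(ev$recording),
               n_ictal = nrow(ev$annotation$ictal_intervals),
               n_artifact = nrow(ev$annotation$artifact_intervals),
               stringsAsFactors = FALSE)
  }))
}
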