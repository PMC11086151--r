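# Shared fixtures, all built in code at test time.

# Recording where every channel carries the same given trace (or per-channel
# constants when `per_channel` is a vector of length 21).
trace_recording <- function(trace = NULL, per_channel = NULL, fs = 250,
                            n = 500) {
  ch <- eeg_channels()
  if (!is.null(trace)) {
    data <- matrix(rep(trace, each = length(ch)), nrow = length(ch))
  } else {
    data <- matrix(rep(per_channel, n), nrow = length(ch))
  }
  eeg_recording(data, fs, ch, subject_id = "subT", event_id = "T1")
}

random_recording <- function(seed, fs = 250, n = 500, sd = 20) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(21 * n, 0, sd), 21, n), fs,
                subject_id = "subR", event_id = paste0("R", seed))
}

# Uniform-colour 8-bit image.
const_image <- function(h, w, rgb) {
  plot_image(array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3)))
}

# Single-derivation montage for calibration tests.
single_derivation_montage <- function(pos = "Fp1", neg = "F7") {
  montage_spec("single", data.frame(label = paste0(pos, "-", neg),
                                    pos = pos, neg = neg,
                                    stringsAsFactors = FALSE))
}

# Linearly separable toy image classes for classifier tests: both classes
# are white images with a dark horizontal band plus pixel noise; the band
# sits in the top half for ES and in the bottom half for PNES.
toy_image_set <- function(n_per_class, px = 64, seed = 1) {
  set.seed(seed)
  mk <- function(cls, i) {
    img <- array(1, dim = c(px, px, 3))
    band <- if (cls == "ES") seq(0.15 * px, 0.35 * px) else
      seq(0.65 * px, 0.85 * px)
    img[band, , ] <- 0.1
    noise <- matrix(runif(px * px, -0.08, 0.08), px, px)
    for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] + noise, 0), 1)
    img
  }
  labels <- rep(c("ES", "PNES"), each = n_per_class)
  images <- lapply(seq_along(labels),
                   function(i) mk(labels[i], i))
  list(images = images, labels = labels)
}

# Published evaluation counts and Table-style reference values shared by
# evaluation tests.
reference_counts <- function() {
  list(site_a = c(tp = 90, fp = 4, fn = 48, tn = 254),
       site_b = c(tp = 390, fp = 155, fn = 18, tn = 802))
}
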