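#' Render configuration for waveform plot images
#'
#' Geometry and style of the clinical-review-style raster renderer. The
#' calibration contract is 1 pixel per microvolt vertically (configurable)
#' and `width_px` pixels spanning `epoch_s` seconds horizontally, so a
#' 1000-pixel, 10-second screen displays at most 100 Hz.
#'
#' Each derivation occupies one horizontal lane of height `lane_spacing_px`;
#' deflections are clipped to the lane band (half a lane spacing either side
#' of the baseline), a deterministic stand-in for the trace overlap clinical
#' viewers allow. Traces are black on white by default, with no gridlines or
#' channel labels, so a classifier cannot shortcut on text.
#'
#' @param width_px Image width in pixels.
#' @param epoch_s Seconds of signal per image (10-12 s clinically).
#' @param px_per_uv Vertical scale, pixels per microvolt.
#' @param lane_spacing_px Vertical distance between adjacent channel
#'   baselines; also the clipping band height.
#' @param margin_px Extra background rows above the first and below the
#'   last lane.
#' @param line_px Trace line thickness in pixels.
#' @param negative_up If `TRUE` (the EEG display convention) negative
#'   microvolts deflect upward on screen.
#' @param trace_rgb,bg_rgb Trace and background colors, 8-bit RGB triples.
#' @return An object of class `render_config`.
#' @export
render_config <- function(width_px = 1000, epoch_s = 10, px_per_uv = 1,
                          lane_spacing_px = 25, margin_px = 0, line_px = 1,
                          negative_up = TRUE,
                          trace_rgb = c(0, 0, 0), bg_rgb = c(255, 255, 255)) {
  if (width_px <= 0 || px_per_uv <= 0 || epoch_s <= 0)
    stop("width_px, px_per_uv and epoch_s must be > 0")
  if (lane_spacing_px < 1 || line_px < 1) stop("pixel sizes must be >= 1")
  structure(list(width_px = as.integer(width_px), epoch_s = epoch_s,
                 px_per_uv = px_per_uv,
                 lane_spacing_px = as.integer(lane_spacing_px),
                 margin_px = as.integer(margin_px),
                 line_px = as.integer(line_px),
                 negative_up = isTRUE(negative_up),
                 trace_rgb = as.integer(trace_rgb),
                 bg_rgb = as.integer(bg_rgb)),
            class = "render_config")
}

#' Plot image container
#'
#' @param pixels Integer array height x width x 3, values 0-255.
#' @param meta List of provenance fields (event, window, montage, config
#'   hash).
#' @return An object of class `plot_image`.
#' @export
plot_image <- function(pixels, meta = list()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be a height x width x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, meta = meta), class = "plot_image")
}

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plot_image> %d x %d px (%s)\n", d[2], d[1],
              x$meta$montage %||% "?"))
  invisible(x)
}

#' @rdname plot_image
#' @param img A `plot_image`.
#' @export
image_width <- function(img) dim(img$pixels)[2]

#' @rdname plot_image
#' @export
image_height <- function(img) dim(img$pixels)[1]

#' Tile a recording into display epochs
#'
#' Lists the maximal set of epoch windows of length `epoch_s` that fit
#' fully inside a recording of the given duration, advancing by `stride_s`.
#'
#' @param duration_s Recording duration, seconds.
#' @param epoch_s Window length, seconds (clinically 10-12 s per screen).
#' @param stride_s Step between window starts; equal to `epoch_s` gives
#'   non-overlapping tiling.
#' @return data.frame with columns `start_s`, `end_s` (half-open windows);
#'   empty, with a warning, when the recording is shorter than one epoch.
#' @export
extract_epochs <- function(duration_s, epoch_s = 10, stride_s = epoch_s) {
  stopifnot(epoch_s > 0, stride_s > 0)
  if (epoch_s > duration_s) {
    warning("recording shorter than one epoch; no windows extracted")
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  starts <- seq(0, duration_s - epoch_s, by = stride_s)
  data.frame(start_s = starts, end_s = starts + epoch_s)
}

# Min-max envelope of mapped row positions per pixel column. Rows are the
# (already scaled, integer) vertical positions of each sample; samples are
# binned to columns by index so every sample contributes to exactly one
# column, and each column's fill range is extended to the previous column's
# closing position for continuity.
column_envelope <- function(rows, width) {
  n <- length(rows)
  col <- floor((seq_len(n) - 1) * width / n) + 1L
  lo <- tapply(rows, col, min)
  hi <- tapply(rows, col, max)
  last <- tapply(rows, col, function(r) r[length(r)])
  idx <- as.integer(names(lo))
  lov <- hiv <- rep(NA_integer_, width)
  lov[idx] <- lo
  hiv[idx] <- hi
  prev <- c(NA, last[-length(last)])
  lov[idx] <- pmin(lov[idx], prev, na.rm = TRUE)
  hiv[idx] <- pmax(hiv[idx], prev, na.rm = TRUE)
  list(lo = lov, hi = hiv)
}

#' Render one epoch of a derived recording as a plot image
#'
#' Draws one horizontal lane per derivation, stacked top to bottom in
#' montage order. Within each pixel column the samples mapping to that
#' column are summarised by their min-max envelope, so extrema survive
#' the downsampling from samples to pixels. Vertical deflection is
#' microvolts times `px_per_uv` around the lane baseline (negative up by
#' default); deflections are clipped to the lane band. Rendering is fully
#' deterministic.
#'
#' @param drec A `derived_recording` from [derive_montage()].
#' @param window A list or one-row data.frame with `start_s`, `end_s`
#'   (half-open, inside the recording).
#' @param cfg A [render_config()].
#' @return A [plot_image()] of height
#'   `n_derivations * lane_spacing_px + 2 * margin_px`.
#' @export
render_epoch <- function(drec, window, cfg = render_config()) {
  stopifnot(inherits(drec, "derived_recording"))
  start_s <- as.numeric(window$start_s)
  end_s <- as.numeric(window$end_s)
  dur <- ncol(drec$data) / drec$fs
  if (start_s < 0 || end_s > dur + 1e-9 || start_s >= end_s)
    stop("window must lie inside the recording")
  nlane <- nrow(drec$data)
  if (nlane == 0L) stop("derived recording has zero derivations")

  i0 <- floor(start_s * drec$fs) + 1L
  i1 <- floor(end_s * drec$fs)
  w <- cfg$width_px
  h <- nlane * cfg$lane_spacing_px + 2L * cfg$margin_px
  px <- array(rep(cfg$bg_rgb, each = h * w), dim = c(h, w, 3))

  pol <- if (cfg$negative_up) 1 else -1   # positive uV drawn downward when negative_up
  half <- cfg$lane_spacing_px / 2
  for (lane in seq_len(nlane)) {
    base <- cfg$margin_px + (lane - 1L) * cfg$lane_spacing_px +
      as.integer(ceiling(cfg$lane_spacing_px / 2))
    rows <- base + as.integer(round(pol * drec$data[lane, i0:i1] * cfg$px_per_uv))
    band_lo <- max(1L, as.integer(ceiling(base - half)))
    band_hi <- min(h, as.integer(floor(base + half)))
    rows <- pmin(pmax(rows, band_lo), band_hi)
    env <- column_envelope(rows, w)
    keep <- which(!is.na(env$lo))
    lo <- pmax(band_lo, env$lo[keep] - (cfg$line_px - 1L) %/% 2L)
    hi <- pmin(band_hi, env$hi[keep] + cfg$line_px %/% 2L)
    len <- hi - lo + 1L
    ridx <- sequence(len, from = lo)
    cidx <- rep(keep, len)
    for (ch in 1:3)
      px[cbind(ridx, cidx, ch)] <- cfg$trace_rgb[ch]
  }
  plot_image(px, meta = list(
    subject_id = drec$subject_id, event_id = drec$event_id,
    montage = drec$montage$name, start_s = start_s, end_s = end_s,
    config_hash = config_hash(unclass(cfg))))
}

#' Maximum frequency displayable on screen
#'
#' The horizontal pixel raster limits the displayed frequency content:
#' with `width_px` pixels spanning `epoch_s` seconds, at most
#' `width_px / epoch_s` cycles per second can be resolved (e.g., 100 Hz
#' for a 1000-pixel, 10-second screen).
#'
#' @param width_px Screen width in pixels.
#' @param epoch_s Seconds of signal displayed.
#' @return Frequency in Hz.
#' @export
display_max_frequency <- function(width_px, epoch_s) {
  if (width_px <= 0 || epoch_s <= 0) stop("width_px and epoch_s must be > 0")
  width_px / epoch_s
}

#' Read and write plot images as PNG
#'
#' @param img A [plot_image()].
#' @param path File path; a sidecar `<path>.json` with the image metadata
#'   is written alongside.
#' @return `write_plot_image()` returns `path` invisibly;
#'   `read_plot_image()` returns a [plot_image()].
#' @export
write_plot_image <- function(img, path) {
  stopifnot(inherits(img, "plot_image"))
  png::writePNG(img$pixels / 255, path)
  jsonlite::write_json(img$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plot_image
#' @export
read_plot_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE] * 255
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  plot_image(round(a), meta = meta)
}
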