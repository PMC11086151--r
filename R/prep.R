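#' Segment preparation configuration
#'
#' Parameters of the segment-level processing chain: split each epoch image
#' into two half-width segments, drop ES segments with too little ictal
#' content, drop EMG-blackened segments by pixel sum, pad to square with
#' the fixed background color, resize to the classifier input size, and
#' normalise to `[0, 1]`.
#'
#' The EMG threshold (18 million summed 8-bit values) is defined at a
#' reference render area of 540,000 px (a 1000-pixel-wide screen with 21
#' lanes at the default spacing); for images of any other area the
#' threshold scales proportionally, and at exactly the reference area the
#' absolute constant applies verbatim.
#'
#' @param emg_threshold Summed 8-bit pixel value below which a segment is
#'   discarded as EMG-contaminated, at the reference area.
#' @param reference_area_px Area (pixels) at which `emg_threshold` is
#'   defined.
#' @param min_ictal_s Minimum seconds of electrographic seizure an ES
#'   segment must contain to be kept.
#' @param pad_rgb 8-bit RGB triple used for square padding. The default
#'   (255, 0, 0), pure red, is the fixed convention of the upstream
#'   preparation recipe this package reproduces.
#' @param target_px Classifier input side length after resizing.
#' @param split_ratios Named proportions for `train`, `validation`, `test`;
#'   must sum to 1.
#' @param seed Seed for the single proportional random split.
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(emg_threshold = 18e6, reference_area_px = 540000,
                        min_ictal_s = 2, pad_rgb = c(255, 0, 0),
                        target_px = 224,
                        split_ratios = c(train = 0.6, validation = 0.2,
                                         test = 0.2),
                        seed = 1L) {
  if (emg_threshold < 0 || min_ictal_s < 0) stop("thresholds must be >= 0")
  if (abs(sum(split_ratios) - 1) > 1e-8) stop("split_ratios must sum to 1")
  structure(list(emg_threshold = emg_threshold,
                 reference_area_px = reference_area_px,
                 min_ictal_s = min_ictal_s,
                 pad_rgb = as.integer(pad_rgb),
                 target_px = as.integer(target_px),
                 split_ratios = split_ratios, seed = as.integer(seed)),
            class = "prep_config")
}

#' Split an epoch image into two equal-width segments
#'
#' A 10-12 s epoch image becomes two 5-6 s segment images of equal width.
#' For odd input widths the final column is discarded. Window metadata on
#' each half covers the corresponding half of the epoch.
#'
#' @param img A [plot_image()].
#' @return List with elements `left` and `right`, both [plot_image()]s of
#'   width `floor(width / 2)`.
#' @export
split_image <- function(img) {
  stopifnot(inherits(img, "plot_image"))
  w <- image_width(img)
  if (w < 2) stop("image width must be >= 2 to split")
  half <- w %/% 2L
  mk <- function(cols, side) {
    meta <- img$meta
    if (!is.null(meta$start_s) && !is.null(meta$end_s)) {
      dt <- (meta$end_s - meta$start_s) / w
      meta$start_s <- img$meta$start_s + (cols[1] - 1) * dt
      meta$end_s <- img$meta$start_s + cols[length(cols)] * dt
    }
    meta$half <- side
    plot_image(img$pixels[, cols, , drop = FALSE], meta)
  }
  list(left = mk(seq_len(half), "left"),
       right = mk(half + seq_len(half), "right"))
}

#' Ictal-content filter
#'
#' Decides whether a segment is kept under the minimum-ictal-content rule:
#' an ES segment must contain at least `min_ictal_s` seconds of
#' electrographic seizure (total overlap between its time window and the
#' annotated ictal intervals); segments of PNES events are always kept by
#' this rule. This annotation-overlap rule is the computable surrogate for
#' the visual review performed in clinical dataset preparation.
#'
#' @param window List or one-row data.frame with `start_s`, `end_s`.
#' @param annotation The event's [event_annotation()].
#' @param min_ictal_s Minimum seconds of ictal content.
#' @return List with `status` (`"kept"` or `"dropped_ictal_rule"`) and
#'   `ictal_overlap_s`.
#' @export
ictal_content_filter <- function(window, annotation, min_ictal_s = 2) {
  if (is.null(annotation)) stop("segment has no event annotation")
  ov <- interval_overlap_s(as.numeric(window$start_s),
                          as.numeric(window$end_s),
                          annotation$ictal_intervals)
  status <- if (annotation$event_type == "ES" && ov < min_ictal_s)
    "dropped_ictal_rule" else "kept"
  list(status = status, ictal_overlap_s = ov)
}

#' EMG pixel-density filter
#'
#' Dense EMG artifact blackens large regions of a waveform plot, driving
#' the summed pixel value of the (white-background) image down. A segment
#' is discarded when the sum over all pixels and all three 8-bit RGB
#' channels falls strictly below the area-scaled threshold; at the
#' reference render area the comparison is exactly against
#' `cfg$emg_threshold`.
#'
#' @param img A [plot_image()] (8-bit RGB).
#' @param cfg A [prep_config()].
#' @return List with `pixel_sum`, `threshold` (area-scaled), and `status`
#'   (`"kept"` or `"dropped_emg"`).
#' @export
emg_density_filter <- function(img, cfg = prep_config()) {
  stopifnot(inherits(img, "plot_image"))
  if (max(img$pixels) > 255 || min(img$pixels) < 0 ||
      any(img$pixels != round(img$pixels)))
    stop("emg_density_filter requires integer 8-bit pixel values")
  area <- image_width(img) * image_height(img)
  threshold <- cfg$emg_threshold * area / cfg$reference_area_px
  pixel_sum <- sum(img$pixels)
  list(pixel_sum = pixel_sum, threshold = threshold,
       status = if (pixel_sum < threshold) "dropped_emg" else "kept")
}

#' Pad an image to square aspect ratio
#'
#' Centres the image on a square canvas of side `max(height, width)`,
#' filling added pixels with `pad_rgb`. Square inputs are returned
#' unchanged.
#'
#' @param img A [plot_image()].
#' @param pad_rgb 8-bit RGB triple for the padding.
#' @return A square [plot_image()].
#' @export
pad_to_square <- function(img, pad_rgb = c(255, 0, 0)) {
  stopifnot(inherits(img, "plot_image"))
  h <- image_height(img)
  w <- image_width(img)
  if (h == w) return(img)
  side <- max(h, w)
  out <- array(rep(as.integer(pad_rgb), each = side * side),
               dim = c(side, side, 3))
  r0 <- (side - h) %/% 2L
  c0 <- (side - w) %/% 2L
  out[r0 + seq_len(h), c0 + seq_len(w), ] <- img$pixels
  plot_image(out, meta = c(img$meta, list(padded_from = c(h, w))))
}

#' Resize to the classifier input size and normalise
#'
#' Bilinearly resizes a square image to `target x target` pixels and
#' divides every 8-bit value by 255. Because bilinear interpolation is
#' linear, resizing and rescaling commute; the result is identical to
#' resizing the 8-bit image first and dividing afterwards.
#'
#' @param img A square [plot_image()].
#' @param target Output side length in pixels.
#' @return Numeric array `target x target x 3` with values in `[0, 1]`.
#' @export
resize_and_normalize <- function(img, target = 224) {
  stopifnot(inherits(img, "plot_image"))
  h <- image_height(img)
  w <- image_width(img)
  if (h != w) stop("input must be square; pad_to_square() first")
  x <- img$pixels / 255
  if (h != target) {
    eb <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
    eb <- EBImage::resize(eb, w = target, h = target)
    x <- aperm(EBImage::imageData(eb), c(2, 1, 3))
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Assign events to train/validation/test splits
#'
#' Randomisation is at the event (seizure video) level: all segments of one
#' event share one split, preventing within-event leakage between training
#' and evaluation. A single seeded proportional draw is made; counts per
#' split use largest-remainder rounding so they sum to the number of
#' events.
#'
#' @param event_ids Character vector of distinct event identifiers.
#' @param ratios Named proportions (`train`, `validation`, `test`) summing
#'   to 1.
#' @param seed Integer seed for the single draw.
#' @return data.frame with columns `event_id`, `split`.
#' @export
assign_splits <- function(event_ids,
                          ratios = c(train = 0.6, validation = 0.2,
                                     test = 0.2),
                          seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  if (anyDuplicated(event_ids)) stop("event_ids must be distinct")
  n <- length(event_ids)
  base <- floor(ratios * n)
  rem <- ratios * n - base
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  perm <- with_seed(seed, sample(n))
  split <- rep(names(ratios), times = base)
  data.frame(event_id = event_ids,
             split = split[order(perm)],
             stringsAsFactors = FALSE)
}

#' Full segment preparation for one epoch image
#'
#' Applies the segment chain in its fixed order — split, ictal-content
#' filter, EMG pixel-density filter, pad, resize, normalise — and returns
#' both the processed tensors (for kept segments) and an auditable record
#' per segment.
#'
#' @param img A [plot_image()] of one rendered epoch.
#' @param annotation The event's [event_annotation()].
#' @param label `"ES"` or `"PNES"`.
#' @param cfg A [prep_config()].
#' @return List of two per-half lists, each with `record` (a one-row
#'   data.frame: `event_id`, `half`, `label`, `start_s`, `end_s`,
#'   `ictal_overlap_s`, `pixel_sum`, `status`) and, when kept, `tensor`
#'   (the normalised `target x target x 3` array).
#' @export
prepare_segments <- function(img, annotation, label, cfg = prep_config()) {
  halves <- split_image(img)
  lapply(halves, function(seg) {
    ic <- ictal_content_filter(list(start_s = seg$meta$start_s,
                                    end_s = seg$meta$end_s),
                               annotation, cfg$min_ictal_s)
    status <- ic$status
    emg <- emg_density_filter(seg, cfg)
    if (status == "kept") status <- emg$status
    tensor <- NULL
    if (status == "kept") {
      sq <- pad_to_square(seg, cfg$pad_rgb)
      tensor <- resize_and_normalize(sq, cfg$target_px)
    }
    record <- data.frame(
      subject_id = seg$meta$subject_id %||% NA_character_,
      event_id = seg$meta$event_id %||% NA_character_,
      montage = seg$meta$montage %||% NA_character_,
      half = seg$meta$half, label = label,
      start_s = seg$meta$start_s, end_s = seg$meta$end_s,
      ictal_overlap_s = ic$ictal_overlap_s,
      pixel_sum = emg$pixel_sum, status = status,
      stringsAsFactors = FALSE)
    list(record = record, tensor = tensor)
  })
}
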