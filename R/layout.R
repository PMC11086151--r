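#' Standard scalp electrode layout
#'
#' The fixed channel layout used throughout the package: the 19 scalp
#' electrodes of the international 10-20 system plus the two inferior
#' temporal electrodes FT9 and FT10, in a fixed documented order
#' (frontal to occipital, left before right, midline, then FT9/FT10).
#'
#' @return Character vector of 21 unique electrode labels.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "FT9", "FT10")
}

#' @rdname eeg_channels
#' @details `scalp_1020_channels()` returns the 19 standard 10-20 scalp
#'   electrodes (FT9/FT10 excluded); this is the electrode set entering the
#'   common-average reference.
#' @export
scalp_1020_channels <- function() {
  setdiff(eeg_channels(), c("FT9", "FT10"))
}
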