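#' Frontal and parietal regions of interest
#'
#' The two a-priori scalp regions used throughout the analyses, named by
#' International 10-5 electrode labels: a frontal strip around Fz/AFz and a
#' parietal patch around Pz/POz.
#'
#' @return Named list with character vectors `frontal` and `parietal`.
#' @export
#' @examples
#' tova_rois()$parietal
tova_rois <- function() {
  list(
    frontal  = c("F4", "F4h", "Fz", "F3h", "F3", "AFF4h", "AFz", "AFF3h"),
    parietal = c("P3", "P1", "CPPz", "P2", "P4", "PO3", "POz", "PO4")
  )
}

#' Default synthetic montage
#'
#' The 16 ROI electrodes plus two mastoid reference channels (M1, M2) and two
#' bipolar EOG channels (VEOG, HEOG). A full high-density montage is not
#' simulated; the ROI channels are the ones every downstream analysis needs.
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c(tova_rois()$frontal, tova_rois()$parietal, "M1", "M2", "VEOG", "HEOG")
}

# EEG (non-EOG) channels of a label set
eeg_channels <- function(labels) setdiff(labels, c("VEOG", "HEOG"))

# resolve a ROI argument (name or label vector) to channel indices
resolve_roi <- function(labels, roi) {
  chans <- if (is.character(roi) && length(roi) == 1L &&
               roi %in% names(tova_rois())) {
    tova_rois()[[roi]]
  } else if (is.list(roi) && !is.null(roi$channels)) {
    roi$channels
  } else {
    as.character(roi)
  }
  if (length(chans) == 0L) stopf("ROI has no channels")
  missing <- setdiff(chans, labels)
  if (length(missing) > 0L) {
    stopf("ROI channel(s) not in recording: %s", paste(missing, collapse = ", "))
  }
  match(chans, labels)
}
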