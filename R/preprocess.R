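#' Zero-phase FIR band-pass filter
#'
#' Applies a windowed-sinc (Hamming) FIR band-pass to every channel of a
#' continuous recording. The default 2-45 Hz band mirrors the standard
#' preprocessing chain for attention-task ERP/oscillation analyses. The
#' symmetric FIR is applied in one pass and its group delay removed, so the
#' net filter is exactly zero phase.
#'
#' @param rec An `eeg_recording`.
#' @param hp_hz,lp_hz High-pass and low-pass corner frequencies (Hz).
#' @param transition_hz Transition band width (Hz); sets the filter length.
#' @return The filtered recording; filter settings recorded in
#'   `rec$params$filter`.
#' @export
filter_band <- function(rec, hp_hz = 2, lp_hz = 45, transition_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < fs / 2)) {
    stopf("need 0 < hp_hz < lp_hz < fs/2 (got %g, %g at fs %g)",
          hp_hz, lp_hz, fs)
  }
  ord <- ceiling(3.3 * fs / transition_hz)  # Hamming transition ~ 3.3/N
  if (ord %% 2 == 1) ord <- ord + 1  # even order -> odd-length symmetric FIR
  b <- signal::fir1(ord, c(hp_hz, lp_hz) / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1))
  gd <- ord / 2
  ns <- ncol(rec$data)
  for (ci in seq_len(nrow(rec$data))) {
    y <- signal::fftfilt(b, c(rec$data[ci, ], rep(0, gd)))
    rec$data[ci, ] <- y[(gd + 1):(gd + ns)]
  }
  rec$params$filter <- list(hp_hz = hp_hz, lp_hz = lp_hz,
                            transition_hz = transition_hz, order = ord)
  rec
}

#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the two reference channels from every EEG channel
#' (EOG channels are left untouched).
#'
#' @param rec An `eeg_recording`.
#' @param ref_labels Two channel labels, by default the mastoids.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, ref_labels = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(ref_labels, rec$channel_labels)
  if (length(missing)) stopf("reference channel(s) missing: %s",
                             paste(missing, collapse = ", "))
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  targets <- eeg_channels(rec$channel_labels)
  rec$data[targets, ] <- sweep(rec$data[targets, , drop = FALSE], 2, ref)
  rec$params$reference <- ref_labels
  rec
}

#' Threshold blink detector on the vertical EOG
#'
#' A deliberately simple convenience detector: samples where |VEOG| exceeds
#' the threshold are merged into intervals and padded. It is not the
#' probabilistic blink-detection procedure used in full preprocessing
#' pipelines; ground-truth or externally supplied annotations should be
#' preferred when available.
#'
#' @param rec An `eeg_recording`.
#' @param channel EOG channel label.
#' @param threshold_uv Detection threshold (microvolts).
#' @param pad_s Padding added to each side of a detected interval (s).
#' @return data.frame of annotations (`kind`, `start_s`, `end_s`).
#' @export
detect_blinks_veog <- function(rec, channel = "VEOG", threshold_uv = 75,
                               pad_s = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$channel_labels) stopf("channel '%s' missing", channel)
  hot <- abs(rec$data[channel, ]) > threshold_uv
  if (!any(hot)) {
    return(data.frame(kind = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  iv <- cbind(starts[keep], ends[keep]) / rec$fs_hz
  iv[, 1] <- pmax(iv[, 1] - pad_s, 0)
  iv[, 2] <- pmin(iv[, 2] + pad_s, ncol(rec$data) / rec$fs_hz)
  # merge overlapping padded intervals
  merged <- list()
  cur <- iv[1, ]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= cur[2]) cur[2] <- max(cur[2], iv[k, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- iv[k, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  data.frame(kind = "blink", start_s = m[, 1], end_s = m[, 2],
             stringsAsFactors = FALSE)
}
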