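#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per stimulus event, spanning the half-open window
#' `[window_s[1], window_s[2])` around stimulus onset (the sample at t = 0
#' belongs to the poststimulus side, so a (-1, 1) s window at 512 Hz yields
#' exactly 1024 samples). Each trial is classified from behavior into
#' correct response, correct inhibition, commission, omission, or invalid
#' (anticipatory response faster than the cutoff). Events too close to a
#' recording edge are dropped with a warning.
#'
#' @param rec An `eeg_recording` whose event table carries `responded` and
#'   `rt_s`.
#' @param window_s Length-2 window around onset, seconds.
#' @param anticipatory_cutoff_s Validity cutoff for response times (s).
#' @return An `epoch_set`: `data` (trials x channels x samples), `time_s`,
#'   `fs_hz`, `channel_labels`, `meta` (per-trial `condition`, `half`,
#'   `rt_s`, `onset_s`), `lock = "stimulus"` and a per-stage `log`.
#' @export
epoch <- function(rec, window_s = c(-1, 1), anticipatory_cutoff_s = 0.15) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  ev <- rec$events
  n_pre <- round(-window_s[1] * fs)
  n_post <- round(window_s[2] * fs)
  len <- n_pre + n_post
  if (len <= 0) stopf("empty epoch window")
  time_s <- (seq_len(len) - 1 - n_pre) / fs
  ns <- ncol(rec$data)
  nch <- nrow(rec$data)

  if (nrow(ev) == 0) {
    return(new_epoch_set(array(0, c(0, nch, len)), time_s, fs,
                         rec$channel_labels, empty_meta(), "stimulus"))
  }
  idx0 <- round(ev$onset_s * fs) + 1L
  start <- idx0 - n_pre
  ok <- start >= 1L & (start + len - 1L) <= ns
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge dropped",
                    sum(!ok)), call. = FALSE)
  }
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  nt <- nrow(ev)
  data <- array(0, c(nt, nch, len))
  for (k in seq_len(nt)) {
    data[k, , ] <- rec$data[, start[k]:(start[k] + len - 1L)]
  }
  cls <- classify_trials(ev, anticipatory_cutoff_s = anticipatory_cutoff_s)
  meta <- data.frame(
    trial_id = ev$trial %||% seq_len(nt),
    condition = cls,
    half = ev$half %||% rep(NA_character_, nt),
    stim = as.character(ev$stim),
    rt_s = ev$rt_s %||% rep(NA_real_, nt),
    onset_s = ev$onset_s,
    stringsAsFactors = FALSE
  )
  es <- new_epoch_set(data, time_s, fs, rec$channel_labels, meta, "stimulus")
  es$log <- data.frame(stage = "epoch", n_in = length(ok), n_out = nt,
                       stringsAsFactors = FALSE)
  es
}

empty_meta <- function() {
  data.frame(trial_id = integer(), condition = character(),
             half = character(), stim = character(), rt_s = numeric(),
             onset_s = numeric(), stringsAsFactors = FALSE)
}

new_epoch_set <- function(data, time_s, fs_hz, channel_labels, meta,
                          lock = "stimulus") {
  structure(
    list(data = data, time_s = time_s, fs_hz = fs_hz,
         channel_labels = channel_labels, meta = meta, lock = lock,
         baseline_interval_s = NULL,
         log = data.frame(stage = character(), n_in = integer(),
                          n_out = integer(), stringsAsFactors = FALSE)),
    class = "epoch_set"
  )
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial index
#' @param epochs An `epoch_set`.
#' @param idx Integer or logical trial selector.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$meta <- epochs$meta[idx, , drop = FALSE]
  rownames(epochs$meta) <- NULL
  epochs
}

#' Concatenate epoch sets along trials
#' @param sets List of `epoch_set`s sharing channels and time axis.
#' @return One combined `epoch_set`.
#' @export
bind_epochs <- function(sets) {
  sets <- Filter(function(s) n_epochs(s) > 0, sets)
  if (length(sets) == 0L) stopf("no epochs to bind")
  ref <- sets[[1]]
  nt <- sum(vapply(sets, n_epochs, 0L))
  d <- dim(ref$data)
  data <- array(0, c(nt, d[2], d[3]))
  at <- 0L
  for (s in sets) {
    k <- n_epochs(s)
    data[(at + 1L):(at + k), , ] <- s$data
    at <- at + k
  }
  ref$data <- data
  ref$meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(ref$meta) <- NULL
  ref$log <- ref$log[0, ]
  ref
}

log_stage <- function(epochs, stage, n_in, n_out) {
  epochs$log <- rbind(epochs$log,
                      data.frame(stage = stage, n_in = n_in, n_out = n_out,
                                 stringsAsFactors = FALSE))
  epochs
}

#' Retrieve the per-stage rejection log
#' @param epochs An `epoch_set`.
#' @return data.frame with `stage`, `n_in`, `n_out`.
#' @export
rejection_log <- function(epochs) epochs$log

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples [%.3g, %.3g) s, %s-locked\n",
              d[1], d[2], d[3], x$time_s[1],
              x$time_s[length(x$time_s)] + 1 / x$fs_hz, x$lock))
  if (d[1] > 0) print(table(x$meta$condition, x$meta$half))
  invisible(x)
}

#' Reject epochs overlapping blink annotations
#'
#' Removes every epoch whose guard window (default -400 to +600 ms around
#' stimulus onset) overlaps a blink interval.
#'
#' @param epochs An `epoch_set` (stimulus-locked).
#' @param annotations data.frame with `kind`, `start_s`, `end_s` in
#'   recording time.
#' @param guard_s Guard window around onset, seconds.
#' @return The pruned `epoch_set`; counts appended to the rejection log.
#' @export
reject_blink_epochs <- function(epochs, annotations, guard_s = c(-0.4, 0.6)) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_in <- n_epochs(epochs)
  blinks <- annotations[annotations$kind == "blink", , drop = FALSE]
  if (nrow(blinks) == 0L || n_in == 0L) {
    return(log_stage(epochs, "blink", n_in, n_in))
  }
  lo <- epochs$meta$onset_s + guard_s[1]
  hi <- epochs$meta$onset_s + guard_s[2]
  bad <- vapply(seq_len(n_in), function(k) {
    any(lo[k] < blinks$end_s & hi[k] > blinks$start_s)
  }, logical(1))
  log_stage(subset_epochs(epochs, !bad), "blink", n_in, sum(!bad))
}

#' Reject epochs by amplitude across channels
#'
#' An epoch is discarded iff its absolute amplitude exceeds the threshold on
#' strictly more than `channel_fraction` of the EEG channels (EOG channels
#' are not counted).
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Amplitude threshold (microvolts).
#' @param channel_fraction Fraction of channels that must exceed it.
#' @return The pruned `epoch_set`; counts appended to the rejection log.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 80,
                             channel_fraction = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold_uv <= 0) stopf("threshold_uv must be > 0")
  n_in <- n_epochs(epochs)
  if (n_in == 0L) return(log_stage(epochs, "amplitude", 0L, 0L))
  chans <- match(eeg_channels(epochs$channel_labels), epochs$channel_labels)
  bad <- vapply(seq_len(n_in), function(k) {
    over <- apply(abs(epochs$data[k, chans, , drop = FALSE]), 2, max) >
      threshold_uv
    mean(over) > channel_fraction
  }, logical(1))
  log_stage(subset_epochs(epochs, !bad), "amplitude", n_in, sum(!bad))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' interval from the whole epoch. The default interval is the full
#' prestimulus second; phase-centred analyses use (-1.0, -0.9) s to keep the
#' baseline clear of the prestimulus window under study.
#'
#' @param epochs An `epoch_set`.
#' @param interval_s Baseline interval `c(lo, hi)` in epoch time.
#' @return The corrected `epoch_set` with `baseline_interval_s` recorded.
#' @export
baseline_correct <- function(epochs, interval_s = c(-1, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- time_window(epochs$time_s, interval_s)
  d <- dim(epochs$data)
  if (d[1] > 0) {
    base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
    epochs$data <- epochs$data - array(base, d)
  }
  epochs$baseline_interval_s <- interval_s
  epochs
}
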