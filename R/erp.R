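#' Per-trial ROI signal
#'
#' Averages an epoch set over the ROI channels, returning a trials x time
#' matrix in microvolts with the epoch time axis attached.
#'
#' @param epochs An `epoch_set`.
#' @param roi ROI name (`"frontal"`/`"parietal"`) or channel label vector.
#' @return Numeric matrix (trials x samples) with attribute `times_s`.
#' @export
roi_signal <- function(epochs, roi) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- resolve_roi(epochs$channel_labels, roi)
  nt <- n_epochs(epochs)
  ns <- dim(epochs$data)[3]
  acc <- matrix(0, nt, ns)
  for (ci in ch) acc <- acc + matrix(epochs$data[, ci, ], nt)
  out <- acc / length(ch)
  attr(out, "times_s") <- epochs$time_s
  out
}

#' Re-epoch to response-locked windows
#'
#' Shifts each responded trial so that time 0 is the button press; trials
#' without a response (or whose shifted window would leave the original
#' epoch) are excluded. The stimulus onset is carried in the metadata as
#' `stim_onset_rel_s = -rt`, so the transform is invertible.
#'
#' @param epochs A stimulus-locked `epoch_set`.
#' @param window_s Response-locked window, seconds (default 1 s centred on
#'   the response).
#' @return A response-locked `epoch_set`.
#' @export
relock_to_response <- function(epochs, window_s = c(-0.5, 0.5)) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs_hz
  has_rt <- !is.na(epochs$meta$rt_s)
  es <- subset_epochs(epochs, has_rt)
  nt <- n_epochs(es)
  n_pre <- round(-window_s[1] * fs)
  n_post <- round(window_s[2] * fs)
  len <- n_pre + n_post
  time_s <- (seq_len(len) - 1 - n_pre) / fs
  # response sample inside the source epoch
  rt_smp <- round(es$meta$rt_s * fs)
  zero_at <- which.min(abs(es$time_s))  # sample index of t = 0
  start <- zero_at + rt_smp - n_pre
  ok <- start >= 1L & (start + len - 1L) <= dim(es$data)[3]
  es <- subset_epochs(es, ok)
  start <- start[ok]
  rt_smp <- rt_smp[ok]
  nt <- n_epochs(es)
  data <- array(0, c(nt, dim(es$data)[2], len))
  for (k in seq_len(nt)) {
    data[k, , ] <- es$data[k, , start[k]:(start[k] + len - 1L)]
  }
  es$data <- data
  es$time_s <- time_s
  es$lock <- "response"
  es$meta$stim_onset_rel_s <- -rt_smp / fs
  es <- log_stage(es, "relock_response", n_epochs(epochs), nt)
  es
}

# Sinkhorn-balanced truncated Gaussian smoothing matrix: symmetric doubly
# stochastic, so identical trials stay identical (rows sum to 1) and the
# column means of the smoothed image equal the grand ERP (columns sum to 1).
smoothing_matrix <- function(n, sd_trials, window_trials, tol = 1e-13,
                             max_iter = 500) {
  h <- max(1L, floor(window_trials / 2))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * max(sd_trials, 1e-3)^2))
  K[d > h] <- 0
  for (i in seq_len(max_iter)) {
    K <- K / rowSums(K)
    K <- t(t(K) / colSums(K))
    if (max(abs(rowSums(K) - 1)) < tol) break
  }
  K <- (K + t(K)) / 2
  K / rowSums(K)
}

#' ERP image: sorted, trial-smoothed amplitude matrix
#'
#' Orders trials by a covariate (RT or prestimulus phase) and smooths
#' vertically with a moving Gaussian whose width is tied to the trial
#' count: SD = n/30 trials, truncated at a window of n/5 trials. The
#' smoothing matrix is balanced to be doubly stochastic, so the column
#' means of the image equal the grand ERP exactly.
#'
#' @param mat Trials x time matrix (e.g. from [roi_signal()]).
#' @param sort_values Per-trial covariate to sort by.
#' @param sort_key Label for the covariate (`"rt"`, `"phase"`, ...).
#' @param sd_trials,window_trials Smoothing parameters; `NULL` applies the
#'   n/30 and n/5 rule.
#' @param lock Lock label carried for display.
#' @return An `erp_image`: smoothed `matrix` (sorted trials x time),
#'   `sort_values` (sorted), `smoothing`, `times_s`, `n_trials`.
#' @export
erp_image <- function(mat, sort_values, sort_key = "rt", sd_trials = NULL,
                      window_trials = NULL, lock = "target") {
  n <- nrow(mat)
  if (n < 2) stopf("an ERP image needs at least 2 trials")
  if (length(sort_values) != n) stopf("sort_values length must match trials")
  sd_trials <- sd_trials %||% (n / 30)
  window_trials <- window_trials %||% (n / 5)
  ord <- order(sort_values)
  K <- smoothing_matrix(n, sd_trials, window_trials)
  structure(
    list(matrix = K %*% mat[ord, , drop = FALSE],
         sort_key = sort_key, sort_values = sort_values[ord],
         trial_index = ord,
         smoothing = list(gaussian_sd_trials = sd_trials,
                          window_trials = window_trials),
         times_s = attr(mat, "times_s"), lock = lock, n_trials = n),
    class = "erp_image"
  )
}

#' @export
print.erp_image <- function(x, ...) {
  cat(sprintf("<erp_image> %d trials sorted by %s, Gaussian SD %.2f trials (window %.1f), %s-locked\n",
              x$n_trials, x$sort_key, x$smoothing$gaussian_sd_trials,
              x$smoothing$window_trials, x$lock))
  invisible(x)
}

#' Grand-average ERP of a trial matrix
#' @param mat Trials x time matrix.
#' @return Numeric vector (time) with `times_s` attribute preserved.
#' @export
grand_erp <- function(mat) {
  out <- colMeans(mat)
  attr(out, "times_s") <- attr(mat, "times_s")
  out
}

#' Median-split grand ERPs
#'
#' Splits trials at the median of a covariate (typically RT) and returns
#' the grand-average ERP of each side; trials at the median go to the
#' below-median side.
#'
#' @param mat Trials x time matrix.
#' @param key Per-trial covariate.
#' @return List with `below`, `above` (mean waveforms), `median`, `n`.
#' @export
median_split_erps <- function(mat, key) {
  n <- nrow(mat)
  if (n < 2) stopf("cannot median-split fewer than 2 trials")
  if (length(key) != n) stopf("key length must match trials")
  med <- stats::median(key)
  below <- key <= med
  if (!any(below) || all(below)) stopf("degenerate split: all trials on one side")
  list(below = colMeans(mat[below, , drop = FALSE]),
       above = colMeans(mat[!below, , drop = FALSE]),
       median = med, n = c(below = sum(below), above = sum(!below)))
}

#' Phase-sorted ERP image
#'
#' For each trial, finds the alpha-band frequency (8-12 Hz by default) with
#' maximum power at the sorting latency (-80 ms), estimates the
#' instantaneous phase there with a single Morlet wavelet, discards the 5%
#' of trials with lowest peak power, sorts the rest by phase ascending from
#' -pi (ties broken by trial index), and smooths as in [erp_image()].
#'
#' @param epochs An `epoch_set` covering the sorting latency.
#' @param roi ROI name or channel labels.
#' @param phase_time_s Latency at which phase is estimated (s).
#' @param band_hz Frequency band searched for the per-trial power peak.
#' @param retain_fraction Fraction of trials (largest power) retained.
#' @param n_freqs Number of candidate frequencies inside the band.
#' @param cycles Wavelet cycles for the phase estimate.
#' @return An `erp_image` (sort_key `"phase"`) with extra fields
#'   `peak_freq_hz`, `power`, and `display_window_s` (first 400 ms
#'   poststimulus, the region where coherent waves concentrate).
#' @export
phase_sort <- function(epochs, roi = "parietal", phase_time_s = -0.08,
                       band_hz = c(8, 12), retain_fraction = 0.95,
                       n_freqs = 9, cycles = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (band_hz[2] >= epochs$fs_hz / 2) stopf("band above Nyquist")
  mat <- roi_signal(epochs, roi)
  n <- nrow(mat)
  if (n < 2) stopf("phase sorting needs at least 2 trials")
  col0 <- time_index(epochs$time_s, phase_time_s)
  freqs <- seq(band_hz[1], band_hz[2], length.out = n_freqs)
  zmat <- matrix(0 + 0i, n, n_freqs)
  for (fi in seq_len(n_freqs)) {
    z <- morlet_convolve(mat, freqs[fi], cycles, epochs$fs_hz)
    zmat[, fi] <- z[, col0]
  }
  pw <- Mod(zmat)^2
  fpk <- max.col(pw, ties.method = "first")
  peak_pw <- pw[cbind(seq_len(n), fpk)]
  phase <- Arg(zmat[cbind(seq_len(n), fpk)])
  n_keep <- floor(retain_fraction * n + 1e-9)
  keep <- order(peak_pw, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)
  img <- erp_image(mat[keep, , drop = FALSE], phase[keep],
                   sort_key = "phase", lock = epochs$lock %||% "stimulus")
  ordk <- order(phase[keep])
  img$trial_index <- keep[img$trial_index]
  img$peak_freq_hz <- freqs[fpk[keep]][ordk]
  img$power <- peak_pw[keep][ordk]
  img$phase_time_s <- phase_time_s
  img$display_window_s <- c(0, 0.4)
  img
}

#' Default amplitude-test windows
#'
#' The N2/P3-centred test windows: 150-250 and 330-430 ms for
#' target-locked trials; -170 to -70 and 0 to 100 ms for response-locked
#' trials.
#'
#' @param lock `"target"` or `"response"`.
#' @return List of length-2 numeric windows (seconds).
#' @export
default_test_windows <- function(lock = c("target", "response")) {
  lock <- match.arg(lock)
  if (lock == "target") list(c(0.150, 0.250), c(0.330, 0.430))
  else list(c(-0.170, -0.070), c(0.0, 0.100))
}

#' Windowed amplitude group test
#'
#' Reduces each trial to its mean ROI amplitude inside each test window and
#' compares the two groups' trial-level distributions with a two-sample
#' Kolmogorov-Smirnov test; p-values are Benjamini-Hochberg corrected
#' across the tested windows. Trial-level pooling within group is the
#' default unit; pass per-participant means as rows for a participant-level
#' test.
#'
#' @param mat_a,mat_b Trials x time matrices (with `times_s` attributes)
#'   for the two groups.
#' @param windows_s List of `c(lo, hi)` windows in epoch time; `NULL` uses
#'   [default_test_windows()] for `lock`.
#' @param lock `"target"` or `"response"` (selects default windows).
#' @param alpha FDR level.
#' @return data.frame with one row per window: `window_lo_s`, `window_hi_s`,
#'   `ks_D`, `p_raw`, `p_fdr`, `significant`, `mean_a_uv`, `mean_b_uv`.
#' @export
window_amplitude_test <- function(mat_a, mat_b, windows_s = NULL,
                                  lock = c("target", "response"),
                                  alpha = 0.05) {
  lock <- match.arg(lock)
  if (nrow(mat_a) == 0 || nrow(mat_b) == 0) stopf("empty group")
  windows_s <- windows_s %||% default_test_windows(lock)
  times <- attr(mat_a, "times_s")
  if (is.null(times)) stopf("mat_a lacks a times_s attribute")
  rows <- lapply(windows_s, function(w) {
    sel <- time_window(times, w)
    a <- rowMeans(mat_a[, sel, drop = FALSE])
    b <- rowMeans(mat_b[, sel, drop = FALSE])
    kt <- ks_two_sample(a, b)
    data.frame(window_lo_s = w[1], window_hi_s = w[2], ks_D = kt$D,
               p_raw = kt$p, mean_a_uv = mean(a), mean_b_uv = mean(b))
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_correct(out$p_raw, alpha = alpha)
  out$p_fdr <- fdr$p_adj
  out$significant <- fdr$reject
  out$lock <- lock
  out[, c("lock", "window_lo_s", "window_hi_s", "ks_D", "p_raw", "p_fdr",
          "significant", "mean_a_uv", "mean_b_uv")]
}
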