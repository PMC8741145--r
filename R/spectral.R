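#' Build the wavelet frequency grid
#'
#' Defines the analysis frequencies and the number of Morlet cycles at each.
#' Cycles scale linearly in frequency between `cycles_spec[1]` at `f_min`
#' and `cycles_spec[1] * (f_max / f_min) * cycles_spec[2]` at `f_max`; with
#' the default (3, 0.5) specification over 4-30 Hz this runs from 3 cycles
#' at 4 Hz to 11.25 cycles at 30 Hz, trading temporal for spectral
#' resolution as frequency rises. Wavelet support is
#' `round(cycles * fs / f)` samples.
#'
#' @param f_min,f_max Frequency range (Hz).
#' @param n_freqs Number of frequencies.
#' @param cycles_spec Length-2 `(base_cycles, scaling_factor)`.
#' @param fs_hz Sampling rate the windows are expressed in.
#' @param spacing `"log"` (default, matches log-frequency display) or
#'   `"linear"`.
#' @return A `freq_grid`: `freqs_hz`, `cycles`, `window_samples`, `fs_hz`.
#' @export
#' @examples
#' g <- build_freq_grid()
#' g$cycles[c(1, length(g$cycles))]  # 3 at 4 Hz, 11.25 at 30 Hz
build_freq_grid <- function(f_min = 4, f_max = 30, n_freqs = 54,
                            cycles_spec = c(3, 0.5), fs_hz = 512,
                            spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!(f_min > 0 && f_max > f_min)) stopf("need 0 < f_min < f_max")
  if (n_freqs < 2) stopf("need at least 2 frequencies")
  if (length(cycles_spec) != 2 || cycles_spec[1] <= 0 || cycles_spec[2] <= 0) {
    stopf("cycles_spec must be positive (base_cycles, scaling_factor)")
  }
  freqs <- if (spacing == "log") {
    exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  } else {
    seq(f_min, f_max, length.out = n_freqs)
  }
  c_min <- cycles_spec[1]
  c_max <- cycles_spec[1] * (f_max / f_min) * cycles_spec[2]
  cycles <- c_min + (freqs - f_min) / (f_max - f_min) * (c_max - c_min)
  structure(
    list(freqs_hz = freqs, cycles = cycles,
         window_samples = round(cycles * fs_hz / freqs), fs_hz = fs_hz),
    class = "freq_grid"
  )
}

#' @export
print.freq_grid <- function(x, ...) {
  n <- length(x$freqs_hz)
  cat(sprintf("<freq_grid> %d freqs %.3g-%.3g Hz, cycles %.3g-%.3g, windows %d-%d samples @ %g Hz\n",
              n, x$freqs_hz[1], x$freqs_hz[n], x$cycles[1], x$cycles[n],
              max(x$window_samples), min(x$window_samples), x$fs_hz))
  invisible(x)
}

# complex Morlet wavelet: Gaussian-tapered exponential, unit L2 norm,
# SD_t = cycles / (2*pi*f), support = round(cycles*fs/f) samples (odd).
morlet_wavelet <- function(freq, cycles, fs) {
  L <- round(cycles * fs / freq)
  if (L %% 2 == 0) L <- L + 1L
  t <- seq(-(L - 1) / 2, (L - 1) / 2) / fs
  sd_t <- cycles / (2 * pi * freq)
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sd_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# FFT convolution of every row of `mat` (trials x samples) with one wavelet;
# returns complex trials x samples aligned to the wavelet centre.
morlet_convolve <- function(mat, freq, cycles, fs) {
  psi <- morlet_wavelet(freq, cycles, fs)
  L <- length(psi)
  h <- (L - 1L) / 2L
  ns <- ncol(mat)
  nt <- nrow(mat)
  nfft <- stats::nextn(ns + L - 1L, 2)
  W <- stats::fft(c(psi, rep(0 + 0i, nfft - L)))
  X <- stats::mvfft(rbind(t(mat), matrix(0, nfft - ns, nt)))
  Y <- stats::mvfft(X * W, inverse = TRUE) / nfft
  t(Y[(h + 1L):(h + ns), , drop = FALSE])
}

# per-frequency power of all trials at selected sample indices, sharing one
# forward FFT per channel matrix across the whole grid
morlet_bank_power <- function(mat, grid, idx) {
  ns <- ncol(mat)
  nt <- nrow(mat)
  Lmax <- max(grid$window_samples) + 1L
  nfft <- stats::nextn(ns + Lmax - 1L, 2)
  X <- stats::mvfft(rbind(t(mat), matrix(0, nfft - ns, nt)))
  nf <- length(grid$freqs_hz)
  out <- array(0, c(nt, nf, length(idx)))
  for (fi in seq_len(nf)) {
    psi <- morlet_wavelet(grid$freqs_hz[fi], grid$cycles[fi], grid$fs_hz)
    L <- length(psi)
    h <- (L - 1L) / 2L
    W <- stats::fft(c(psi, rep(0 + 0i, nfft - L)))
    Y <- stats::mvfft(X * W, inverse = TRUE) / nfft
    z <- t(Y[(h + idx), , drop = FALSE])  # trials x centres
    out[, fi, ] <- Mod(z)^2
  }
  out
}

# 200 (default) linearly spaced time centres over the valid (unpadded)
# region, defined by the largest wavelet in the grid
tfr_times <- function(grid, time_s, n_times = 200) {
  half <- max(grid$window_samples) / (2 * grid$fs_hz)
  lo <- time_s[1] + half
  hi <- time_s[length(time_s)] - half
  if (lo >= hi) stopf("epoch too short for the largest wavelet (%d samples)",
                      max(grid$window_samples))
  seq(lo, hi, length.out = n_times)
}

#' Morlet time-frequency decomposition of one signal
#'
#' Convolves a single time series with the complex Morlet bank of a
#' frequency grid and evaluates it at time centres spanning the valid
#' (edge-free) region.
#'
#' @param x Numeric signal.
#' @param grid A [build_freq_grid()] result.
#' @param time_s Time axis of `x` (seconds); defaults to samples from 0.
#' @param n_times Number of time centres.
#' @return List with complex `coef` (freq x time), `power`, `phase`,
#'   `freqs_hz`, `times_s`.
#' @export
morlet_tfr <- function(x, grid, time_s = NULL, n_times = 200) {
  stopifnot(inherits(grid, "freq_grid"))
  if (is.null(time_s)) time_s <- (seq_along(x) - 1) / grid$fs_hz
  if (length(x) < max(grid$window_samples)) {
    stopf("signal shorter than the largest wavelet (%d samples)",
          max(grid$window_samples))
  }
  times <- tfr_times(grid, time_s, n_times)
  idx <- time_index(time_s, times)
  nf <- length(grid$freqs_hz)
  coef <- matrix(0 + 0i, nf, length(idx))
  mat <- matrix(x, 1)
  for (fi in seq_len(nf)) {
    z <- morlet_convolve(mat, grid$freqs_hz[fi], grid$cycles[fi], grid$fs_hz)
    coef[fi, ] <- z[1, idx]
  }
  list(coef = coef, power = Mod(coef)^2, phase = Arg(coef),
       freqs_hz = grid$freqs_hz, times_s = times)
}

#' Per-trial ROI time-frequency power
#'
#' Computes the Morlet TFR for each ROI electrode individually and averages
#' power across electrodes per trial. Averaging power (not signals)
#' preserves activity whose phase differs between electrodes; the TFR of
#' the channel average would cancel it.
#'
#' @param epochs An `epoch_set`.
#' @param roi ROI name (`"frontal"`/`"parietal"`) or channel label vector.
#' @param grid A [build_freq_grid()] result.
#' @param n_times Number of time centres.
#' @return A `roi_power`: `power` (trials x freq x time), `freqs_hz`,
#'   `times_s`, `roi`, `n_trials`.
#' @export
roi_tfr <- function(epochs, roi, grid, n_times = 200) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "freq_grid"))
  ch <- resolve_roi(epochs$channel_labels, roi)
  times <- tfr_times(grid, epochs$time_s, n_times)
  idx <- time_index(epochs$time_s, times)
  nt <- n_epochs(epochs)
  if (nt < 1) stopf("no epochs")
  nf <- length(grid$freqs_hz)
  pow <- array(0, c(nt, nf, length(idx)))
  for (ci in ch) {
    mat <- matrix(epochs$data[, ci, ], nt)
    pow <- pow + morlet_bank_power(mat, grid, idx)
  }
  structure(
    list(power = pow / length(ch), freqs_hz = grid$freqs_hz, times_s = times,
         roi = if (is.character(roi) && length(roi) == 1) roi else "custom",
         n_trials = nt, fs_hz = grid$fs_hz),
    class = "roi_power"
  )
}

new_tfr_set <- function(kind, power_lin, baseline, rp, baseline_s) {
  db <- 10 * log10(sweep(power_lin, 1, baseline, "/"))
  structure(
    list(kind = kind, power_db = db, power_lin = power_lin,
         baseline = baseline, baseline_interval_s = baseline_s,
         freqs_hz = rp$freqs_hz, times_s = rp$times_s, roi = rp$roi,
         n_trials = rp$n_trials),
    class = "tfr_set"
  )
}

#' @export
print.tfr_set <- function(x, ...) {
  cat(sprintf("<tfr_set:%s> %d freqs x %d times, ROI %s, %d trials, dB vs [%.3g, %.3g) s baseline\n",
              x$kind, length(x$freqs_hz), length(x$times_s), x$roi,
              x$n_trials, x$baseline_interval_s[1], x$baseline_interval_s[2]))
  invisible(x)
}

# baseline columns: times inside interval (default: whole prestimulus part)
baseline_cols <- function(times_s, baseline_s) {
  if (is.null(baseline_s)) baseline_s <- c(times_s[1] - 1e-9, 0)
  sel <- times_s >= baseline_s[1] & times_s < baseline_s[2]
  if (!any(sel)) stopf("baseline interval contains no TFR time centres")
  list(sel = sel, interval = c(max(times_s[1], baseline_s[1]), baseline_s[2]))
}

#' Event-related spectral perturbation (total power)
#'
#' Averages per-trial linear power over trials and expresses it in dB
#' relative to the mean prestimulus baseline power per frequency
#' (`10 * log10(P / P_baseline)`), a divisive per-frequency baseline.
#'
#' @param rp A [roi_tfr()] result.
#' @param baseline_s Baseline interval in epoch time; `NULL` for the whole
#'   prestimulus part of the TFR time axis.
#' @return A `tfr_set` with `kind = "total"`.
#' @export
ersp <- function(rp, baseline_s = NULL) {
  stopifnot(inherits(rp, "roi_power"))
  P <- apply(rp$power, c(2, 3), mean)
  bc <- baseline_cols(rp$times_s, baseline_s)
  base <- rowMeans(P[, bc$sel, drop = FALSE])
  new_tfr_set("total", P, base, rp, bc$interval)
}

# shared helper: mean power over trials and channels for arbitrary 3d data
mean_tfr_power <- function(data3d, ch, grid, idx) {
  nt <- dim(data3d)[1]
  nf <- length(grid$freqs_hz)
  acc <- matrix(0, nf, length(idx))
  for (ci in ch) {
    pow <- morlet_bank_power(matrix(data3d[, ci, ], nt), grid, idx)
    acc <- acc + apply(pow, c(2, 3), mean)
  }
  acc / length(ch)
}

#' Evoked (phase-locked) power
#'
#' The TFR of the across-trial time-domain average (the classic ERP),
#' computed per electrode then averaged across the ROI, in dB against its
#' own prestimulus baseline.
#'
#' @inheritParams roi_tfr
#' @param baseline_s Baseline interval; `NULL` for the prestimulus part.
#' @return A `tfr_set` with `kind = "evoked"`.
#' @export
evoked_power <- function(epochs, roi, grid, n_times = 200, baseline_s = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- resolve_roi(epochs$channel_labels, roi)
  nt <- n_epochs(epochs)
  if (nt < 1) stopf("no epochs")
  times <- tfr_times(grid, epochs$time_s, n_times)
  idx <- time_index(epochs$time_s, times)
  erp <- apply(epochs$data, c(2, 3), mean)  # channels x samples
  P <- mean_tfr_power(aperm(array(erp, c(dim(erp), 1)), c(3, 1, 2)), ch,
                      grid, idx)
  rp <- list(freqs_hz = grid$freqs_hz, times_s = times,
             roi = if (is.character(roi) && length(roi) == 1) roi else "custom",
             n_trials = nt)
  bc <- baseline_cols(times, baseline_s)
  base <- rowMeans(P[, bc$sel, drop = FALSE])
  new_tfr_set("evoked", P, base, rp, bc$interval)
}

#' Induced (non-phase-locked) power
#'
#' Subtracts the grand-average ERP from every epoch per electrode in the
#' time domain, computes per-trial TFRs, and averages over trials and ROI
#' electrodes; dB convention as in [ersp()].
#'
#' @inheritParams evoked_power
#' @return A `tfr_set` with `kind = "induced"`.
#' @export
induced_power <- function(epochs, roi, grid, n_times = 200,
                          baseline_s = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_epochs(epochs)
  if (nt < 2) stopf("induced power needs at least 2 trials")
  ch <- resolve_roi(epochs$channel_labels, roi)
  times <- tfr_times(grid, epochs$time_s, n_times)
  idx <- time_index(epochs$time_s, times)
  erp <- apply(epochs$data, c(2, 3), mean)
  resid <- epochs$data - aperm(array(erp, c(dim(erp), nt)), c(3, 1, 2))
  P <- mean_tfr_power(resid, ch, grid, idx)
  rp <- list(freqs_hz = grid$freqs_hz, times_s = times,
             roi = if (is.character(roi) && length(roi) == 1) roi else "custom",
             n_trials = nt)
  bc <- baseline_cols(times, baseline_s)
  base <- rowMeans(P[, bc$sel, drop = FALSE])
  new_tfr_set("induced", P, base, rp, bc$interval)
}

# cycles at an arbitrary frequency under the default linear-cycles rule
cycles_at <- function(freq, f_min = 4, f_max = 30, cycles_spec = c(3, 0.5)) {
  c_min <- cycles_spec[1]
  c_max <- cycles_spec[1] * (f_max / f_min) * cycles_spec[2]
  c_min + (freq - f_min) / (f_max - f_min) * (c_max - c_min)
}

#' Intertrial coherence at one frequency
#'
#' ITC(t) is the magnitude of the across-trial mean unit phase vector at the
#' analysis frequency, computed per channel and then averaged across
#' channels: 0 for uniformly random phases (chance level ~ sqrt(pi)/(2
#' sqrt(n))), 1 for perfect phase locking.
#'
#' @param epochs An `epoch_set`.
#' @param channels ROI name or channel labels (default: parietal ROI).
#' @param freq_hz Analysis frequency (default 10 Hz alpha).
#' @param cycles Wavelet cycles; `NULL` applies the default grid cycle rule.
#' @param n_times Number of time centres.
#' @param keep_phase Keep the per-trial phase arrays (needed by
#'   [itc_significance()] internally).
#' @return An `itc_series`: `freq_hz`, `times_s`, `itc`, `n_trials`, and
#'   optionally `phase` (list per channel of trials x time unit vectors).
#' @export
itc <- function(epochs, channels = "parietal", freq_hz = 10, cycles = NULL,
                n_times = 200, keep_phase = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_epochs(epochs)
  if (nt < 2) stopf("ITC needs at least 2 trials")
  ch <- resolve_roi(epochs$channel_labels, channels)
  if (is.null(cycles)) cycles <- cycles_at(freq_hz)
  fs <- epochs$fs_hz
  win <- round(cycles * fs / freq_hz)
  grid1 <- list(window_samples = win, fs_hz = fs)
  times <- tfr_times(grid1, epochs$time_s, n_times)
  idx <- time_index(epochs$time_s, times)
  units <- vector("list", length(ch))
  acc <- numeric(length(idx))
  for (k in seq_along(ch)) {
    mat <- matrix(epochs$data[, ch[k], ], nt)
    z <- morlet_convolve(mat, freq_hz, cycles, fs)[, idx, drop = FALSE]
    m <- Mod(z)
    u <- z / ifelse(m > 0, m, 1)
    units[[k]] <- u
    acc <- acc + Mod(complex(real = .colMeans(Re(u), nt, length(idx)),
                             imaginary = .colMeans(Im(u), nt, length(idx))))
  }
  structure(
    list(freq_hz = freq_hz, times_s = times, itc = acc / length(ch),
         n_trials = nt, cycles = cycles,
         phase = if (keep_phase) units else NULL,
         sig_mask = NULL, alpha = NULL),
    class = "itc_series"
  )
}

#' @export
print.itc_series <- function(x, ...) {
  cat(sprintf("<itc_series> %g Hz, %d times, %d trials, peak %.3f%s\n",
              x$freq_hz, length(x$times_s), x$n_trials, max(x$itc),
              if (!is.null(x$sig_mask))
                sprintf(", %d significant points", sum(x$sig_mask)) else ""))
  invisible(x)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodograms with one-sided density scaling. Each
#' row of `x` is treated as an independent segment source (e.g. one trial
#' and channel); rows shorter than the window clip the window to the row
#' length (overlap rescaled to 75%), as used for the 500 ms prestimulus
#' alpha analysis.
#'
#' @param x Numeric vector or matrix (rows = segments).
#' @param fs_hz Sampling rate.
#' @param window FFT window length in samples (default 512 = 1 s at 512 Hz).
#' @param overlap Overlap between successive windows in samples.
#' @param freq_range Frequency band to report, Hz (inclusive).
#' @param segment Label recorded in the result (`"baseline"`,
#'   `"poststimulus"`, ...).
#' @return A `psd_estimate`: `freqs_hz`, `power` (linear density, uV^2/Hz),
#'   `log_power_db`, `n_segments`, `window_samples`, `overlap_samples`.
#' @export
welch_psd <- function(x, fs_hz, window = 512, overlap = 384,
                      freq_range = c(4, 16), segment = "unspecified") {
  if (is.vector(x)) x <- matrix(x, 1)
  len <- ncol(x)
  if (len < 16) stopf("segment too short for spectral estimation")
  if (len < window) {
    window <- len
    overlap <- floor(0.75 * window)
  }
  step <- window - overlap
  if (step < 1) stopf("overlap must be smaller than the window")
  starts <- seq(1, len - window + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / (window - 1))
  U <- sum(w^2)
  nfreq <- window %/% 2 + 1
  acc <- numeric(nfreq)
  nseg <- 0L
  for (r in seq_len(nrow(x))) {
    for (s in starts) {
      seg <- x[r, s:(s + window - 1)]
      seg <- (seg - mean(seg)) * w
      S <- stats::fft(seg)[seq_len(nfreq)]
      pxx <- Mod(S)^2 / (fs_hz * U)
      pxx[2:(nfreq - 1)] <- 2 * pxx[2:(nfreq - 1)]  # one-sided
      acc <- acc + pxx
      nseg <- nseg + 1L
    }
  }
  P <- acc / nseg
  freqs <- seq(0, nfreq - 1) * fs_hz / window
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2]
  structure(
    list(freqs_hz = freqs[sel], power = P[sel],
         log_power_db = 10 * log10(P[sel]), segment = segment,
         window_samples = window, overlap_samples = overlap,
         n_segments = nseg),
    class = "psd_estimate"
  )
}

#' Welch PSD of an epoch interval
#'
#' Extracts one interval from every epoch and channel and feeds the
#' segments to [welch_psd()], e.g. the baseline and poststimulus seconds,
#' or the 500 ms prestimulus window for the alpha-band analysis.
#'
#' @param epochs An `epoch_set`.
#' @param channels ROI name or channel labels.
#' @param interval_s Interval in epoch time, `c(lo, hi)`.
#' @inheritParams welch_psd
#' @return A `psd_estimate`.
#' @export
welch_psd_epochs <- function(epochs, channels = "parietal",
                             interval_s = c(0, 1), window = 512,
                             overlap = 384, freq_range = c(4, 16),
                             segment = "unspecified") {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- resolve_roi(epochs$channel_labels, channels)
  sel <- time_window(epochs$time_s, interval_s)
  nt <- n_epochs(epochs)
  if (nt == 0) stopf("no epochs")
  rows <- matrix(0, nt * length(ch), sum(sel))
  r <- 0L
  for (ci in ch) {
    rows[r + seq_len(nt), ] <- matrix(epochs$data[, ci, sel], nt)
    r <- r + nt
  }
  welch_psd(rows, epochs$fs_hz, window, overlap, freq_range, segment)
}
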