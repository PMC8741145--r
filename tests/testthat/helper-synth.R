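# shared fixtures and independent oracles, all built in code

# epoch_set from a trials x time matrix (single channel) or 3d array
synthetic_epochs <- function(mat = NULL, data3d = NULL, fs = 512,
                             channel_labels = "P3", t0_frac = 0.5,
                             conditions = "correct_response", halves = "H1",
                             rt = NA_real_, onsets = NULL) {
  if (is.null(data3d)) {
    data3d <- array(mat, c(nrow(mat), 1, ncol(mat)))
  }
  nt <- dim(data3d)[1]
  ns <- dim(data3d)[3]
  time_s <- (seq_len(ns) - 1 - round(ns * t0_frac)) / fs
  meta <- data.frame(
    trial_id = seq_len(nt),
    condition = rep_len(conditions, nt),
    half = rep_len(halves, nt),
    stim = rep_len("target", nt),
    rt_s = rep_len(rt, nt),
    onset_s = onsets %||% (seq_len(nt) * 2),
    stringsAsFactors = FALSE
  )
  tovaosc:::new_epoch_set(data3d, time_s, fs, channel_labels, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# epochs of pure cosines at one frequency with per-trial phases (phase is
# the signal phase at t = 0)
pure_sine_epochs <- function(phases, freq = 10, fs = 512, dur = 1.25,
                             amp = 1, channel_labels = "P3") {
  ns <- round(dur * fs)
  tt <- (seq_len(ns) - 1 - round(ns * 0.5)) / fs
  mat <- t(vapply(phases, function(p) amp * cos(2 * pi * freq * tt + p),
                  numeric(ns)))
  es <- synthetic_epochs(mat, fs = fs, channel_labels = channel_labels)
  es
}

# analytic-signal envelope via FFT (independent of the wavelet path)
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# brute-force two-sample KS statistic from the ECDF definition
ks_D_oracle <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

# hand-rolled Benjamini-Hochberg step-up adjusted p-values
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Fisher-Lee circular correlation
circ_cor <- function(a, b) {
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sum(sin(a - am) * sin(b - bm)) /
    sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
}

# one-channel recording wrapper for filter tests
single_channel_recording <- function(x, fs = 512, label = "Pz") {
  structure(
    list(data = matrix(x, 1, dimnames = list(label, NULL)), fs_hz = fs,
         channel_labels = label,
         events = data.frame(), annotations = data.frame(), params = list()),
    class = "eeg_recording"
  )
}
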