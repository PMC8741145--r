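#' Generator parameters for synthetic TOVA-EEG
#'
#' Collects every tunable of the synthetic recording: sampling rate, montage,
#' 1/f background noise, ongoing ~10 Hz alpha with stimulus-locked phase
#' resetting, Gaussian-windowed half-sine evoked components (N2/P3-like),
#' theta amplitude modulations (8 Hz prestimulus, 4 Hz poststimulus), and
#' blink artifacts. Amplitudes are in microvolts.
#'
#' The phase reset is a fractional pull: at each stimulus onset plus
#' `reset_latency_s` the ongoing alpha phase moves toward `reset_phase` by the
#' fraction `phase_reset_strength` of the circular distance, so strength 1
#' aligns every trial exactly and strength 0 leaves phases at chance.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param channels Channel label vector; defaults to the 16 ROI channels plus
#'   mastoids and EOG.
#' @param noise_exponent Spectral slope of the 1/f background (power ~ 1/f^a).
#' @param noise_scale_uv RMS amplitude of the background noise per channel.
#' @param alpha_hz,alpha_amp_pre Ongoing alpha frequency and amplitude.
#' @param phase_jitter Random-walk phase increment SD (rad/sample); sets the
#'   alpha linewidth and how fast post-reset coherence decays.
#' @param phase_reset_strength Pull fraction in \[0, 1\].
#' @param reset_latency_s Latency of the reset after stimulus onset (s).
#' @param reset_phase Target phase of the reset (rad).
#' @param erp_components List of components, each
#'   `list(label, latency_s, width_s, amplitude_uv, sign)`; a Gaussian-windowed
#'   half-sine deflection added at every stimulus onset.
#' @param theta8_base_amp,theta8_pre_amp,theta8_pre_window_s 8 Hz amplitude
#'   outside/inside the prestimulus window (s, relative to onset).
#' @param theta4_base_amp,theta4_post_amp,theta4_post_duration_s 4 Hz
#'   amplitude outside/inside the poststimulus window `[0, duration]`.
#' @param blink_rate_per_min,blink_amp_uv,blink_duration_s Blink artifact
#'   rate, VEOG amplitude, and duration; blinks are also recorded as ground
#'   truth annotations.
#' @param pad_s Quiet padding before the first and after the last trial so
#'   every trial supports a full epoch window.
#' @param seed Integer seed; equal seeds give bit-identical recordings.
#' @return A `gen_params` list.
#' @export
gen_params <- function(fs_hz = 512, channels = default_montage(),
                       noise_exponent = 1, noise_scale_uv = 3,
                       alpha_hz = 10, alpha_amp_pre = 4,
                       phase_jitter = 0.04,
                       phase_reset_strength = 0.5, reset_latency_s = 0.05,
                       reset_phase = 0,
                       erp_components = list(
                         list(label = "N2", latency_s = 0.20, width_s = 0.05,
                              amplitude_uv = 5, sign = -1),
                         list(label = "P3", latency_s = 0.38, width_s = 0.09,
                              amplitude_uv = 8, sign = 1)
                       ),
                       theta8_base_amp = 1.5, theta8_pre_amp = 3,
                       theta8_pre_window_s = c(-0.6, -0.1),
                       theta4_base_amp = 3, theta4_post_amp = 4.2,
                       theta4_post_duration_s = 0.7,
                       blink_rate_per_min = 3, blink_amp_uv = 150,
                       blink_duration_s = 0.3,
                       pad_s = 1, seed = 1L) {
  p <- list(fs_hz = fs_hz, channels = channels,
            noise_exponent = noise_exponent, noise_scale_uv = noise_scale_uv,
            alpha_hz = alpha_hz, alpha_amp_pre = alpha_amp_pre,
            phase_jitter = phase_jitter,
            phase_reset_strength = phase_reset_strength,
            reset_latency_s = reset_latency_s, reset_phase = reset_phase,
            erp_components = erp_components,
            theta8_base_amp = theta8_base_amp, theta8_pre_amp = theta8_pre_amp,
            theta8_pre_window_s = theta8_pre_window_s,
            theta4_base_amp = theta4_base_amp, theta4_post_amp = theta4_post_amp,
            theta4_post_duration_s = theta4_post_duration_s,
            blink_rate_per_min = blink_rate_per_min, blink_amp_uv = blink_amp_uv,
            blink_duration_s = blink_duration_s,
            pad_s = pad_s, seed = seed)
  if (p$phase_reset_strength < 0 || p$phase_reset_strength > 1) {
    stopf("phase_reset_strength must be in [0, 1]")
  }
  amps <- c(p$noise_scale_uv, p$alpha_amp_pre, p$theta8_base_amp,
            p$theta8_pre_amp, p$theta4_base_amp, p$theta4_post_amp,
            vapply(p$erp_components, function(cc) cc$amplitude_uv, 0))
  if (any(amps < 0)) stopf("amplitudes must be >= 0")
  if (p$fs_hz <= 2 * max(p$alpha_hz, 8, 4)) {
    stopf("fs_hz must exceed twice the highest synthesized frequency")
  }
  class(p) <- "gen_params"
  p
}

#' Group presets for the synthetic generator
#'
#' Two parameter sets emulating the qualitative group contrasts under study:
#' `"control"` has larger evoked components, an earlier and stronger alpha
#' phase reset, a stronger poststimulus 4 Hz and prestimulus 8 Hz theta
#' modulation; `"adhd"` has weaker/later resetting, smaller evoked
#' amplitudes, weaker theta modulation and elevated prestimulus alpha power.
#'
#' @param group `"control"` or `"adhd"`.
#' @param ... Overrides passed to [gen_params()].
#' @return A `gen_params` list.
#' @export
group_preset <- function(group = c("control", "adhd"), ...) {
  group <- match.arg(group)
  base <- if (group == "control") {
    list(phase_reset_strength = 0.7, reset_latency_s = 0.05,
         alpha_amp_pre = 3.5,
         theta8_pre_amp = 3.2, theta4_post_amp = 4.8,
         erp_components = list(
           list(label = "N2", latency_s = 0.20, width_s = 0.05,
                amplitude_uv = 5, sign = -1),
           list(label = "P3", latency_s = 0.36, width_s = 0.09,
                amplitude_uv = 8, sign = 1)))
  } else {
    list(phase_reset_strength = 0.35, reset_latency_s = 0.09,
         alpha_amp_pre = 4.8,
         theta8_pre_amp = 2.0, theta4_post_amp = 3.6,
         erp_components = list(
           list(label = "N2", latency_s = 0.22, width_s = 0.05,
                amplitude_uv = 3.5, sign = -1),
           list(label = "P3", latency_s = 0.42, width_s = 0.10,
                amplitude_uv = 6, sign = 1)))
  }
  do.call(gen_params, utils::modifyList(base, list(...)))
}

# 1/f noise by spectral shaping of white noise, rescaled to unit RMS
noise_1f <- function(n, fs, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  fk <- pmin(k, n - k) * fs / n  # two-sided frequency magnitude
  g <- c(0, fk[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Gaussian-windowed half-sine deflection template, support [lat-w, lat+w]
erp_template <- function(comp, fs) {
  w <- comp$width_s
  t <- seq(comp$latency_s - w, comp$latency_s + w, by = 1 / fs)
  halfsine <- sin(pi * (t - (comp$latency_s - w)) / (2 * w))
  taper <- exp(-(t - comp$latency_s)^2 / (2 * (w / 2)^2))
  list(offset = round((comp$latency_s - w) * fs),
       shape = comp$sign * comp$amplitude_uv * halfsine * taper)
}

# smooth-edged rectangular envelope (cosine ramps), sampled on t (s)
ramp_window <- function(t, lo, hi, ramp = 0.05) {
  up <- stats::plogis((t - lo) / (ramp / 4))
  down <- stats::plogis((hi - t) / (ramp / 4))
  up * down
}

#' Synthesize a continuous TOVA-EEG recording
#'
#' Builds a multichannel recording with known ground truth from a trial
#' schedule, simulated behavior and generator parameters. The signal is the
#' sum of per-channel 1/f noise, a shared ongoing alpha oscillation whose
#' phase performs a random walk and is pulled toward a fixed phase shortly
#' after every stimulus onset, evoked N2/P3-like transients at each onset,
#' and theta oscillations with trial-locked amplitude envelopes (8 Hz
#' elevated prestimulus, 4 Hz elevated poststimulus) at random phase per
#' trial. Mastoids carry attenuated noise only; EOG channels carry noise and
#' blinks. Blink times are returned as ground-truth annotations.
#'
#' @param schedule A [make_schedule()] result.
#' @param behavior Optional [simulate_behavior()] result for the schedule;
#'   merged into the event table.
#' @param params A [gen_params()] list.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts, rownames = labels), `fs_hz`, `channel_labels`, `events`
#'   (trial table with onsets in recording time), `annotations` (blink
#'   intervals), and `params`.
#' @export
#' @examples
#' sch <- make_schedule("H1", 4, 12, seed = 1)
#' rec <- synthesize_eeg(sch, simulate_behavior(sch, seed = 1),
#'                       gen_params(seed = 1, blink_rate_per_min = 0))
#' dim(rec$data)
synthesize_eeg <- function(schedule, behavior = NULL, params = gen_params()) {
  stopifnot(inherits(schedule, "tova_schedule"), inherits(params, "gen_params"))
  fs <- params$fs_hz
  labels <- params$channels
  nch <- length(labels)
  dur <- 2 * params$pad_s + schedule$duration_s
  n <- round(dur * fs)
  tr <- schedule$trials
  onsets <- tr$onset_s + params$pad_s
  onset_idx <- round(onsets * fs) + 1L

  is_eog <- labels %in% c("VEOG", "HEOG")
  is_mastoid <- labels %in% c("M1", "M2")
  sig_gain <- ifelse(is_eog | is_mastoid, 0, 1)
  noise_gain <- ifelse(is_mastoid, 0.3, ifelse(is_eog, 0.5, 1))

  with_seed(params$seed, {
    data <- matrix(0, nch, n, dimnames = list(labels, NULL))
    if (params$noise_scale_uv > 0) {
      for (ci in seq_len(nch)) {
        data[ci, ] <- noise_gain[ci] * params$noise_scale_uv *
          noise_1f(n, fs, params$noise_exponent)
      }
    }

    shared <- numeric(n)  # signal common to all EEG channels

    # ongoing alpha with stimulus-locked phase resets
    if (params$alpha_amp_pre > 0) {
      dphi <- 2 * pi * params$alpha_hz / fs +
        stats::rnorm(n, 0, params$phase_jitter)
      phi <- cumsum(dphi) + stats::runif(1, 0, 2 * pi)
      s <- params$phase_reset_strength
      if (s > 0 && nrow(tr) > 0) {
        reset_idx <- onset_idx + round(params$reset_latency_s * fs)
        reset_idx <- reset_idx[reset_idx >= 1 & reset_idx <= n]
        offset <- 0
        deltas <- numeric(length(reset_idx))
        for (k in seq_along(reset_idx)) {
          cur <- phi[reset_idx[k]] + offset
          deltas[k] <- s * wrap_angle(params$reset_phase - cur)
          offset <- offset + deltas[k]
        }
        # piecewise-constant cumulative offset applied from each reset on
        bounds <- c(reset_idx, n + 1L)
        off_series <- rep(c(0, cumsum(deltas)), times = diff(c(1L, bounds)))
        phi <- phi + off_series
      }
      shared <- shared + params$alpha_amp_pre * cos(phi)
    }

    # evoked components at every stimulus onset
    if (length(params$erp_components) > 0 && nrow(tr) > 0) {
      templates <- lapply(params$erp_components, erp_template, fs = fs)
      for (tp in templates) {
        L <- length(tp$shape)
        for (oi in onset_idx) {
          a <- oi + tp$offset
          b <- a + L - 1L
          if (a >= 1L && b <= n) {
            shared[a:b] <- shared[a:b] + tp$shape
          }
        }
      }
    }

    # theta amplitude modulations, random phase per trial
    if (nrow(tr) > 0) {
      half_win <- round(fs)  # one SOA-half each side, matches epoch span
      t_rel <- seq(-half_win, half_win - 1L) / fs
      env8 <- params$theta8_base_amp +
        (params$theta8_pre_amp - params$theta8_base_amp) *
        ramp_window(t_rel, params$theta8_pre_window_s[1],
                    params$theta8_pre_window_s[2])
      env4 <- params$theta4_base_amp +
        (params$theta4_post_amp - params$theta4_base_amp) *
        ramp_window(t_rel, 0, params$theta4_post_duration_s)
      for (k in seq_along(onset_idx)) {
        a <- onset_idx[k] - half_win
        b <- onset_idx[k] + half_win - 1L
        lo <- max(a, 1L); hi <- min(b, n)
        seg <- (lo - a + 1L):(length(t_rel) - (b - hi))
        ph8 <- stats::runif(1, 0, 2 * pi)
        ph4 <- stats::runif(1, 0, 2 * pi)
        burst <- env8[seg] * sin(2 * pi * 8 * t_rel[seg] + ph8) +
          env4[seg] * sin(2 * pi * 4 * t_rel[seg] + ph4)
        shared[lo:hi] <- shared[lo:hi] + burst
      }
    }

    data <- data + outer(sig_gain, shared)

    # blinks: raised-cosine artifacts on VEOG and (attenuated) frontal sites
    annotations <- data.frame(kind = character(), start_s = numeric(),
                              end_s = numeric(), stringsAsFactors = FALSE)
    if (params$blink_rate_per_min > 0 && dur > 2) {
      n_blink <- stats::rpois(1, params$blink_rate_per_min * dur / 60)
      if (n_blink > 0) {
        bt <- sort(stats::runif(n_blink, 1, dur - 1 - params$blink_duration_s))
        Lb <- round(params$blink_duration_s * fs)
        shape <- params$blink_amp_uv * 0.5 *
          (1 - cos(2 * pi * seq_len(Lb) / Lb))
        frontal <- labels %in% tova_rois()$frontal
        veog <- labels == "VEOG"
        for (b0 in bt) {
          a <- round(b0 * fs) + 1L
          idx <- a:(a + Lb - 1L)
          data[veog, idx] <- data[veog, idx] + shape
          if (any(frontal)) {
            data[frontal, idx] <- data[frontal, idx] +
              matrix(0.25 * shape, sum(frontal), Lb, byrow = TRUE)
          }
        }
        annotations <- data.frame(kind = "blink", start_s = bt,
                                  end_s = bt + params$blink_duration_s,
                                  stringsAsFactors = FALSE)
      }
    }

    events <- tr
    events$onset_s <- onsets
    if (!is.null(behavior)) {
      stopifnot(nrow(behavior) == nrow(tr))
      events$responded <- behavior$responded
      events$rt_s <- behavior$rt_s
    } else {
      events$responded <- NA
      events$rt_s <- NA_real_
    }

    structure(
      list(data = data, fs_hz = fs, channel_labels = labels,
           events = events, annotations = annotations, params = params),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz), %d events, %d annotations\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs_hz, x$fs_hz,
              nrow(x$events), nrow(x$annotations)))
  invisible(x)
}
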