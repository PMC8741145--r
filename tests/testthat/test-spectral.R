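test_that("the cycle rule interpolates linearly between its printed anchors", {
  g <- build_freq_grid()
  expect_equal(length(g$freqs_hz), 54)
  expect_equal(g$freqs_hz[1], 4)
  expect_equal(g$freqs_hz[54], 30)
  expect_equal(g$cycles[1], 3)
  expect_equal(g$cycles[54], 11.25)
  expect_true(all(diff(g$freqs_hz) > 0))
  expect_true(all(diff(g$cycles) > 0))
  expect_equal(g$window_samples, round(g$cycles * 512 / g$freqs_hz))
  # scaling factor 1 over an octave doubles the cycles: constant duration
  g2 <- build_freq_grid(5, 10, 11, cycles_spec = c(3, 1),
                        spacing = "linear")
  expect_equal(g2$cycles[11], 6)
  expect_equal(g2$window_samples[1], g2$window_samples[11])
  expect_error(build_freq_grid(10, 4), "f_min")
  expect_error(build_freq_grid(cycles_spec = c(-1, 0.5)), "cycles_spec")
})

test_that("Morlet decomposition localizes stationary and stepped signals", {
  fs <- 512
  g <- build_freq_grid(fs_hz = fs)
  ns <- 1024
  tt <- (seq_len(ns) - 1 - 512) / fs
  # pure 10 Hz: power peaks at the nearest grid frequency, flat over time
  tf <- morlet_tfr(cos(2 * pi * 10 * tt), g, time_s = tt, n_times = 60)
  fpk <- g$freqs_hz[apply(tf$power, 2, which.max)]
  expect_true(all(abs(fpk - 10) < 0.5))
  p10 <- tf$power[which.min(abs(g$freqs_hz - 10)), ]
  expect_lt(stats::sd(p10) / mean(p10), 0.01)
  # zero signal: all power zero
  expect_equal(max(morlet_tfr(numeric(ns), g, time_s = tt)$power), 0)
  # amplitude step x2 at t = 0 on a 4 Hz carrier: poststimulus over
  # prestimulus power ratio -> 4 (6.02 dB), cross-checked against an
  # analytic-signal (Hilbert) envelope oracle
  amp <- ifelse(tt < 0, 1, 2)
  x <- amp * cos(2 * pi * 4 * tt)
  tf4 <- morlet_tfr(x, g, time_s = tt, n_times = 120)
  fi <- which.min(abs(g$freqs_hz - 4))
  pre <- mean(tf4$power[fi, tf4$times_s > -0.45 & tf4$times_s < -0.25])
  post <- mean(tf4$power[fi, tf4$times_s > 0.25 & tf4$times_s < 0.45])
  expect_equal(10 * log10(post / pre), 6.02, tolerance = 0.05)
  env <- hilbert_env(x)
  env_pre <- mean(env[tt > -0.45 & tt < -0.25]^2)
  env_post <- mean(env[tt > 0.25 & tt < 0.45]^2)
  expect_equal(10 * log10(post / pre), 10 * log10(env_post / env_pre),
               tolerance = 0.1)
  # the transition occupies roughly one wavelet duration
  prof <- tf4$power[fi, ] / post
  trans <- range(tf4$times_s[prof > 0.3 & prof < 0.9])
  expect_lt(diff(trans), 1.5 * g$window_samples[fi] / fs)
  expect_error(morlet_tfr(numeric(100), g), "shorter")
})

test_that("per-electrode averaging preserves power that channel averaging cancels", {
  fs <- 512
  ns <- 1024
  tt <- (seq_len(ns) - 1 - 512) / fs
  g <- build_freq_grid(n_freqs = 12, fs_hz = fs)
  x <- 3 * cos(2 * pi * 10 * tt)
  d <- array(0, c(1, 2, ns))
  d[1, 1, ] <- x
  d[1, 2, ] <- -x  # opposite phase
  es <- synthetic_epochs(data3d = d, channel_labels = c("P3", "P4"))
  fi <- which.min(abs(g$freqs_hz - 10))
  rp <- roi_tfr(es, c("P3", "P4"), g, n_times = 30)
  # single-electrode reference power
  d1 <- es; d1$data <- d[, 1, , drop = FALSE]; d1$channel_labels <- "P3"
  rp1 <- roi_tfr(d1, "P3", g, n_times = 30)
  expect_equal(rp$power[1, fi, ], rp1$power[1, fi, ], tolerance = 1e-10)
  # TFR of the channel average is nothing
  avg <- es
  avg$data <- array((d[, 1, ] + d[, 2, ]) / 2, c(1, 1, ns))
  avg$channel_labels <- "Pz"
  rp_avg <- roi_tfr(avg, "Pz", g, n_times = 30)
  expect_lt(max(rp_avg$power[1, fi, ]), 1e-20)
  # identical channels: averaging is a no-op
  d2 <- array(0, c(1, 2, ns))
  d2[1, 1, ] <- x
  d2[1, 2, ] <- x
  es2 <- synthetic_epochs(data3d = d2, channel_labels = c("P3", "P4"))
  rp2 <- roi_tfr(es2, c("P3", "P4"), g, n_times = 30)
  expect_equal(rp2$power[1, fi, ], rp1$power[1, fi, ], tolerance = 1e-10)
  # Jensen property on arbitrary data: ROI power >= power of the average
  set.seed(5)
  d3 <- array(rnorm(4 * 2 * ns), c(4, 2, ns))
  es3 <- synthetic_epochs(data3d = d3, channel_labels = c("P3", "P4"))
  rp3 <- roi_tfr(es3, c("P3", "P4"), g, n_times = 30)
  avg3 <- es3
  avg3$data <- array((d3[, 1, ] + d3[, 2, ]) / 2, c(4, 1, ns))
  avg3$channel_labels <- "Pz"
  rpa3 <- roi_tfr(avg3, "Pz", g, n_times = 30)
  expect_true(all(rp3$power - rpa3$power >= -1e-12))
})

test_that("ERSP is flat for stationary signals and definitional for one trial", {
  fs <- 512
  ns <- 1024
  tt <- (seq_len(ns) - 1 - 512) / fs
  g <- build_freq_grid(n_freqs = 10, fs_hz = fs)
  set.seed(6)
  mat <- t(vapply(runif(20, -pi, pi),
                  function(p) 2 * cos(2 * pi * 10 * tt + p), numeric(ns)))
  es <- synthetic_epochs(mat, channel_labels = "P3")
  e <- ersp(roi_tfr(es, "P3", g, n_times = 40))
  expect_lt(max(abs(e$power_db)), 0.5)  # ~0 dB everywhere
  # one trial: ERSP equals that trial's baseline-referenced TFR
  es1 <- synthetic_epochs(mat[1, , drop = FALSE], channel_labels = "P3")
  rp1 <- roi_tfr(es1, "P3", g, n_times = 40)
  e1 <- ersp(rp1)
  base <- rowMeans(rp1$power[1, , rp1$times_s < 0])
  expect_equal(e1$power_db, 10 * log10(rp1$power[1, , ] / base),
               tolerance = 1e-12)
})

test_that("evoked and induced power obey their defining identities", {
  fs <- 512
  ns <- 512
  tt <- (seq_len(ns) - 1 - 256) / fs
  g <- build_freq_grid(n_freqs = 12, fs_hz = fs)
  x <- 3 * cos(2 * pi * 10 * tt) * exp(-tt^2 / 0.05) + 2 * cos(2 * pi * 6 * tt)
  es <- synthetic_epochs(matrix(rep(x, each = 8), 8, byrow = FALSE),
                         channel_labels = "P3")
  es$data[] <- rep(x, each = 8)
  tot <- ersp(roi_tfr(es, "P3", g, n_times = 30))
  ev <- evoked_power(es, "P3", g, n_times = 30)
  ind <- induced_power(es, "P3", g, n_times = 30)
  # identical noise-free trials: evoked = total exactly, induced = 0
  expect_equal(ev$power_lin, tot$power_lin, tolerance = 1e-12)
  expect_lt(max(ind$power_lin), 1e-22)
  # single trial: evoked = total
  es1 <- synthetic_epochs(matrix(x, 1), channel_labels = "P3")
  expect_equal(evoked_power(es1, "P3", g, n_times = 30)$power_lin,
               ersp(roi_tfr(es1, "P3", g, n_times = 30))$power_lin,
               tolerance = 1e-12)
  expect_error(induced_power(es1, "P3", g), "at least 2")
  # random-phase oscillation: evoked shrinks like 1/n, induced ~ total
  set.seed(7)
  ph <- runif(150, -pi, pi)
  mat <- t(vapply(ph, function(p) 2 * cos(2 * pi * 10 * tt + p), numeric(ns)))
  esr <- synthetic_epochs(mat, channel_labels = "P3")
  fi <- which.min(abs(g$freqs_hz - 10))
  totr <- ersp(roi_tfr(esr, "P3", g, n_times = 30))
  evr <- evoked_power(esr, "P3", g, n_times = 30)
  indr <- induced_power(esr, "P3", g, n_times = 30)
  expect_lt(max(evr$power_lin[fi, ] / totr$power_lin[fi, ]), 0.1)
  expect_lt(max(abs(10 * log10(indr$power_lin[fi, ] / totr$power_lin[fi, ]))),
            0.5)
  # the three-way decomposition closes only approximately; report, not assume
  gap <- abs(totr$power_lin[fi, ] - indr$power_lin[fi, ] - evr$power_lin[fi, ])
  expect_lt(max(gap / totr$power_lin[fi, ]), 0.1)
})

test_that("ITC hits its exact and distributional anchors", {
  # identical trials: ITC = 1 everywhere
  es <- pure_sine_epochs(rep(0.7, 12))
  expect_equal(itc(es, "P3", n_times = 30)$itc, rep(1, 30), tolerance = 1e-9)
  # equally spaced phases: the mean vector vanishes
  es0 <- pure_sine_epochs(seq(0, 2 * pi, length.out = 9)[-9])
  expect_lt(max(itc(es0, "P3", n_times = 30)$itc), 1e-9)
  # uniform random phases, n = 100: mean ITC near the Rayleigh mean
  set.seed(8)
  m <- vapply(1:25, function(i) {
    mean(itc(pure_sine_epochs(runif(100, -pi, pi)), "P3", n_times = 20)$itc)
  }, numeric(1))
  expect_equal(mean(m), sqrt(pi) / (2 * sqrt(100)), tolerance = 0.15)
  expect_error(itc(pure_sine_epochs(0.1), "P3"), "at least 2")
})

test_that("Welch PSD has the printed segmentation and Parseval scaling", {
  fs <- 512
  tt <- (seq_len(1024) - 1) / fs
  x <- sin(2 * pi * 10 * tt)
  ps <- welch_psd(x, fs)
  expect_equal(ps$n_segments, 5)  # (1024 - 512) / 128 + 1
  expect_equal(ps$freqs_hz[which.max(ps$log_power_db)], 10)
  expect_equal(diff(ps$freqs_hz)[1], 1)  # 1 Hz bins
  # band-integrated power of a unit sinusoid is A^2/2 within 5%
  full <- welch_psd(x, fs, freq_range = c(0, fs / 2))
  expect_equal(sum(full$power) * (fs / 512), 0.5, tolerance = 0.05)
  # white noise: spectrum flat within Monte-Carlo limits
  set.seed(9)
  wn <- welch_psd(matrix(rnorm(100 * 512), 100), fs, freq_range = c(4, 100))
  expect_lt(max(abs(wn$log_power_db - mean(wn$log_power_db))), 1)
  # short prestimulus segments clip the window
  half <- welch_psd(x[1:256], fs, freq_range = c(8, 12))
  expect_equal(half$window_samples, 256)
  expect_error(welch_psd(x[1:8], fs), "too short")
})
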