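test_that("ROI signals are channel means over the ROI", {
  d <- array(0, c(2, 3, 8))
  d[1, 1, ] <- 1; d[1, 2, ] <- -1; d[1, 3, ] <- 5
  d[2, 1, ] <- 2; d[2, 2, ] <- 4;  d[2, 3, ] <- 9
  es <- synthetic_epochs(data3d = d, channel_labels = c("P3", "P4", "Fz"))
  # single-channel ROI is the identity
  expect_equal(unname(roi_signal(es, "Fz")[, 1]), c(5, 9))
  # antisymmetric channels cancel
  expect_equal(max(abs(roi_signal(es, c("P3", "P4"))[1, ])), 0)
  # plain arithmetic mean otherwise
  expect_equal(unname(roi_signal(es, c("P3", "P4"))[2, 1]), 3)
  expect_error(roi_signal(es, c("P3", "POz")), "not in recording")
})

test_that("response relocking shifts time zero to the button press", {
  fs <- 512
  ns <- 1024
  tt <- (seq_len(ns) - 1 - 512) / fs
  # signature waveform so alignment can be traced exactly
  mat <- rbind(sin(2 * pi * 3 * tt), cos(2 * pi * 5 * tt))
  es <- synthetic_epochs(mat, rt = c(0.4, 0.25))
  rl <- relock_to_response(es)
  # onsets recorded on the sample grid
  expect_equal(rl$meta$stim_onset_rel_s, -round(c(0.4, 0.25) * fs) / fs)
  # value at response-locked time t equals stimulus-locked value at t + rt
  for (k in 1:2) {
    rt_snap <- round(es$meta$rt_s[k] * fs) / fs
    src <- es$data[k, 1, tovaosc:::time_index(es$time_s, rt_snap + c(-0.2, 0, 0.2))]
    dst <- rl$data[k, 1, tovaosc:::time_index(rl$time_s, c(-0.2, 0, 0.2))]
    expect_equal(dst, src)
  }
  # no responses -> empty output
  es_inh <- synthetic_epochs(mat, conditions = "correct_inhibition",
                             rt = NA_real_)
  expect_equal(n_epochs(relock_to_response(es_inh)), 0)
  # equal RTs: relocked grand ERP is the shifted stimulus-locked grand ERP
  es_eq <- synthetic_epochs(mat, rt = 0.25)
  rl_eq <- relock_to_response(es_eq)
  shift <- round(0.25 * fs)
  src_cols <- tovaosc:::time_index(es_eq$time_s, rl_eq$time_s + shift / fs)
  expect_equal(colMeans(rl_eq$data[, 1, ]),
               colMeans(es_eq$data[, 1, src_cols]))
})

test_that("ERP images follow the n/30 smoothing rule and preserve structure", {
  set.seed(11)
  n <- 150
  mat <- matrix(rnorm(n * 64), n)
  attr(mat, "times_s") <- (1:64) / 512
  img <- erp_image(mat, runif(n))
  expect_equal(img$smoothing$gaussian_sd_trials, 5)   # 150 / 30
  expect_equal(img$smoothing$window_trials, 30)       # 150 / 5
  # column means equal the grand ERP regardless of sorting and smoothing
  expect_equal(colMeans(img$matrix), colMeans(mat), tolerance = 1e-9)
  # identical trials stay identical after smoothing
  one <- matrix(rep(sin((1:64) / 5), each = 20), 20)
  img1 <- erp_image(one, runif(20))
  expect_equal(img1$matrix, matrix(rep(sin((1:64) / 5), each = 20), 20),
               tolerance = 1e-9, ignore_attr = TRUE)
  # a step across sorted trials blurs over roughly the Gaussian SD
  stepm <- matrix(rep(c(0, 1), each = 75 * 64), ncol = 64, byrow = FALSE)
  stepm <- rbind(matrix(0, 75, 64), matrix(1, 75, 64))
  imgs <- erp_image(stepm, seq_len(150))
  prof <- imgs$matrix[, 1]
  width <- sum(prof > 0.1 & prof < 0.9)
  expect_gt(width, 5)       # wider than a hard step
  expect_lt(width, 4 * 5)   # but confined to a few SDs
  expect_error(erp_image(mat[1, , drop = FALSE], 1), "at least 2")
  expect_error(erp_image(mat, runif(3)), "length")
})

test_that("median-split ERPs separate amplitude-RT coupling", {
  base <- sin((1:64) / 4)
  mat <- t(vapply(1:40, function(k) base * (1 + 0.02 * k), numeric(64)))
  rt <- seq(0.2, 0.6, length.out = 40)  # amplitude grows with RT here
  ms <- median_split_erps(mat, rt)
  expect_equal(unname(ms$n), c(20, 20))
  expect_lt(mean(abs(ms$below)), mean(abs(ms$above)))
  # identical waveforms: both sides agree
  same <- matrix(rep(base, each = 10), 10)
  ms2 <- median_split_erps(same, rnorm(10))
  expect_equal(ms2$below, ms2$above)
  expect_error(median_split_erps(mat[1, , drop = FALSE], 0.3), "fewer than 2")
})

test_that("phase sorting recovers generator phases and the retention rule", {
  fs <- 512
  ns <- 1024
  tt <- (seq_len(ns) - 1 - 512) / fs
  set.seed(21)
  ph <- runif(100, -pi, pi)  # true phase at the -80 ms sort latency
  mat <- t(vapply(ph, function(p) 4 * cos(2 * pi * 10 * (tt + 0.08) + p),
                  numeric(ns)))
  es <- synthetic_epochs(mat, channel_labels = "P3")
  img <- phase_sort(es, "P3")
  expect_equal(img$n_trials, 95)  # 95% of 100 trials retained
  expect_equal(img$sort_key, "phase")
  expect_false(is.unsorted(img$sort_values))
  # recovered phases match ground truth circularly
  truth <- ph[img$trial_index]
  expect_gt(circ_cor(img$sort_values, truth), 0.95)
  expect_gt(abs(cor(rank(img$sort_values), rank(truth))), 0.9)
  # identical phases: image is uniform across trials
  mat0 <- matrix(rep(4 * cos(2 * pi * 10 * (tt + 0.08)), each = 20), 20,
                 byrow = FALSE)
  mat0 <- t(vapply(1:20, function(i) 4 * cos(2 * pi * 10 * (tt + 0.08)),
                   numeric(ns)))
  es0 <- synthetic_epochs(mat0, channel_labels = "P3")
  img0 <- phase_sort(es0, "P3")
  expect_lt(max(apply(img0$matrix, 2, stats::sd)), 1e-8)
  expect_error(phase_sort(es, "P3", band_hz = c(8, 400)), "Nyquist")
})

test_that("windowed amplitude tests detect shifts and agree with the ECDF oracle", {
  set.seed(31)
  ns <- 512
  times <- (seq_len(ns) - 1 - 256) / 512
  mk <- function(n, shift = 0) {
    m <- matrix(rnorm(n * ns), n) + shift
    attr(m, "times_s") <- times
    m
  }
  a <- mk(200)
  # A against itself: D = 0, p = 1, never significant
  same <- window_amplitude_test(a, a, lock = "target")
  expect_equal(same$ks_D, c(0, 0))
  expect_equal(same$p_raw, c(1, 1))
  expect_false(any(same$significant))
  # a 3 uV shift at n = 200/group survives FDR easily
  b <- mk(200, shift = 3)
  sh <- window_amplitude_test(a, b, lock = "target")
  expect_true(all(sh$significant))
  expect_true(all(sh$p_fdr >= sh$p_raw))
  # response-locked windows default to the printed pre/post intervals
  expect_equal(default_test_windows("response"),
               list(c(-0.170, -0.070), c(0.0, 0.100)))
  expect_error(window_amplitude_test(a[0, , drop = FALSE], b), "empty")
})
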