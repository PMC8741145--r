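test_that("band-pass filter attenuates stopband and preserves passband", {
  fs <- 512
  n <- fs * 20
  tt <- (seq_len(n) - 1) / fs
  mid <- (fs * 5):(fs * 15)  # steady-state region

  r60 <- filter_band(single_channel_recording(sin(2 * pi * 60 * tt)))
  expect_lt(20 * log10(max(abs(r60$data[1, mid]))), -20)

  r10 <- filter_band(single_channel_recording(sin(2 * pi * 10 * tt)))
  expect_lt(abs(max(abs(r10$data[1, mid])) - 1), 0.05)

  rdc <- filter_band(single_channel_recording(rep(5, n)))
  expect_lt(max(abs(rdc$data[1, mid])), 0.05)

  expect_error(filter_band(r10, hp_hz = 50, lp_hz = 45), "hp_hz")
})

test_that("mastoid re-referencing subtracts the reference mean", {
  mk <- function(vals) {
    data <- matrix(vals, 3, 10)
    rownames(data) <- c("Fz", "M1", "M2")
    structure(list(data = data, fs_hz = 512,
                   channel_labels = c("Fz", "M1", "M2"),
                   events = data.frame(), annotations = data.frame(),
                   params = list()),
              class = "eeg_recording")
  }
  # refs identically zero: data unchanged
  r0 <- rereference(mk(c(5, 0, 0)))
  expect_equal(r0$data["Fz", ], rep(5, 10))
  # common mode removed entirely
  rc <- rereference(mk(c(7, 7, 7)))
  expect_equal(max(abs(rc$data)), 0)
  # toy arithmetic: 5 - mean(1, 3) = 3
  rt <- rereference(mk(c(5, 1, 3)))
  expect_equal(rt$data["Fz", ], rep(3, 10))
  expect_error(rereference(mk(c(1, 2, 3)), c("M1", "TP9")), "missing")
})

test_that("epoching cuts half-open windows and classifies trials", {
  sch <- make_schedule("H1", 5, 15, seed = 1)
  beh <- simulate_behavior(sch, list(p_hit = 1, p_commission = 0,
                                     p_anticipatory = 0), seed = 2)
  rec <- synthesize_eeg(sch, beh, gen_params(seed = 3,
                                             blink_rate_per_min = 0))
  es <- epoch(rec)
  expect_equal(n_epochs(es), 20)
  expect_equal(dim(es$data)[3], 1024)
  expect_equal(es$time_s[1], -1)
  expect_equal(es$time_s[1024], 1 - 1 / 512)
  # anticipatory response flagged invalid
  rec2 <- rec
  rec2$events$rt_s[rec2$events$stim == "target"][1] <- 0.10
  es2 <- epoch(rec2)
  expect_equal(as.character(es2$meta$condition[
    which(rec2$events$stim == "target")[1]]), "invalid")
  # empty event table -> empty epoch set
  rec3 <- rec
  rec3$events <- rec3$events[0, ]
  expect_equal(n_epochs(epoch(rec3)), 0)
  # event at the very edge is dropped with a warning
  rec4 <- rec
  rec4$events$onset_s[1] <- 0.2
  expect_warning(es4 <- epoch(rec4), "edge")
  expect_equal(n_epochs(es4), 19)
})

test_that("blink and amplitude rejection follow the stated rules", {
  mat <- matrix(0, 5, 1024)
  es <- synthetic_epochs(
    data3d = array(0, c(3, 10, 1024)),
    channel_labels = c(tova_rois()$parietal, "Fz", "VEOG"),
    onsets = c(10, 20, 30))
  # blink at +0.5 s overlaps the (-0.4, 0.6) guard; +0.7 s does not
  ann <- data.frame(kind = "blink",
                    start_s = c(10.5, 20.7), end_s = c(10.55, 20.75))
  out <- reject_blink_epochs(es, ann)
  expect_equal(out$meta$onset_s, c(20, 30))
  expect_equal(n_epochs(reject_blink_epochs(es, ann[0, ])), 3)

  # amplitude: 100 uV on 60% of channels discarded, on 10% retained
  d <- array(0, c(3, 10, 100))
  d[1, 1:6, ] <- 100   # 6 of 9 EEG channels (VEOG not counted)
  d[2, 1, ] <- 100     # 1 of 9
  esa <- synthetic_epochs(data3d = d,
                          channel_labels = c(tova_rois()$parietal, "Fz",
                                             "VEOG"))
  outa <- reject_amplitude(esa, threshold_uv = 80)
  expect_equal(outa$meta$trial_id, c(2L, 3L))  # all-zero epoch retained too
})

test_that("rejection operators are idempotent and commute on disjoint criteria", {
  set.seed(7)
  d <- array(rnorm(6 * 10 * 256, sd = 10), c(6, 10, 256))
  d[2, 1:8, ] <- 200  # amplitude artifact
  es <- synthetic_epochs(data3d = d,
                         channel_labels = c(tova_rois()$parietal, "Fz",
                                            "VEOG"),
                         onsets = seq(10, 60, by = 10))
  ann <- data.frame(kind = "blink", start_s = 40.1, end_s = 40.2)
  a1 <- reject_amplitude(reject_blink_epochs(es, ann))
  a2 <- reject_blink_epochs(reject_amplitude(es), ann)
  a3 <- reject_amplitude(a1)  # idempotent
  expect_equal(a1$meta$trial_id, a2$meta$trial_id)
  expect_equal(a3$meta$trial_id, a1$meta$trial_id)
  expect_equal(n_epochs(a1), 4)
})

test_that("baseline correction zeroes the interval mean and keeps contrasts", {
  es <- synthetic_epochs(matrix(5, 4, 1024))
  out <- baseline_correct(es)
  expect_equal(max(abs(out$data)), 0)
  set.seed(1)
  es2 <- synthetic_epochs(matrix(rnorm(4 * 1024), 4))
  out2 <- baseline_correct(es2, c(-1, 0))
  sel <- es2$time_s >= -1 & es2$time_s < 0
  expect_lt(max(abs(apply(out2$data[, 1, sel], 1, mean))), 1e-12)
  # within-epoch differences between any two samples unchanged
  expect_equal(out2$data[, 1, 100] - out2$data[, 1, 700],
               es2$data[, 1, 100] - es2$data[, 1, 700])
  # phase-analysis mode uses the (-1.0, -0.9) interval
  out3 <- baseline_correct(es2, c(-1, -0.9))
  expect_equal(out3$baseline_interval_s, c(-1, -0.9))
  sel3 <- es2$time_s >= -1 & es2$time_s < -0.9
  expect_lt(max(abs(apply(out3$data[, 1, sel3], 1, mean))), 1e-12)
  expect_error(baseline_correct(es2, c(0.5, 0.5)), "interval")
})

test_that("epoch extraction reproduces the continuous segments exactly", {
  sch <- make_schedule("H1", 3, 5, seed = 2)
  rec <- synthesize_eeg(sch, NULL, gen_params(seed = 4,
                                              blink_rate_per_min = 0))
  es <- epoch(rec)
  fs <- rec$fs_hz
  for (k in seq_len(n_epochs(es))) {
    i0 <- round(es$meta$onset_s[k] * fs) + 1
    seg <- rec$data[, (i0 - fs):(i0 + fs - 1)]
    expect_equal(es$data[k, , ], unname(seg))
  }
})

test_that("balanced draws honour quotas, exclusions and the 108-epoch rule", {
  mk <- function(n_resp_h1, n_inh_h1, n_resp_h2 = 0, n_inh_h2 = 0) {
    cond <- c(rep("correct_response", n_resp_h1),
              rep("correct_inhibition", n_inh_h1),
              rep("correct_response", n_resp_h2),
              rep("correct_inhibition", n_inh_h2))
    half <- c(rep("H1", n_resp_h1 + n_inh_h1),
              rep("H2", n_resp_h2 + n_inh_h2))
    n <- length(cond)
    synthetic_epochs(data3d = array(0, c(n, 1, 64)), conditions = cond,
                     halves = half, onsets = seq_len(n))
  }
  # 40 available vs quota 36 -> 36 drawn
  b1 <- balance_epochs(mk(40, 80), seed = 1)
  expect_equal(b1$report$drawn[b1$report$condition == "correct_response"], 36)
  # 35 available -> excluded for that condition, drawn = 0
  b2 <- balance_epochs(mk(35, 80), seed = 1)
  r2 <- b2$report[b2$report$condition == "correct_response", ]
  expect_false(r2$included)
  expect_equal(r2$drawn, 0)
  # retained in both H1 conditions -> 36 + 72 = 108 epochs
  b3 <- balance_epochs(mk(50, 90), seed = 2)
  expect_equal(n_epochs(b3$epochs), 108)
  # reproducible under one seed; drawn ids are a subset of available
  b4 <- balance_epochs(mk(50, 90), seed = 2)
  expect_identical(b3$epochs$meta$trial_id, b4$epochs$meta$trial_id)
  expect_true(all(b3$epochs$meta$trial_id %in% seq_len(140)))
})

test_that("sampling stability is zero without sampling freedom", {
  es <- synthetic_epochs(
    data3d = array(rep(rnorm(64), each = 45), c(45, 1, 64)),
    channel_labels = "P3",
    conditions = rep(c("correct_response", "correct_inhibition"),
                     c(15, 30)))
  # identical epochs: any draw gives the same statistic
  st <- sampling_stability(es, quotas = c(infrequent = 10, frequent = 20),
                           n_draws = 5,
                           statistic = function(e) mean(e$data),
                           seed = 1)
  expect_equal(st$mean_variance, 0)
  # available == quota: every draw selects all epochs
  set.seed(3)
  es2 <- synthetic_epochs(
    data3d = array(rnorm(12 * 64), c(12, 1, 64)),
    conditions = rep(c("correct_response", "correct_inhibition"), c(4, 8)))
  st2 <- sampling_stability(es2, quotas = c(infrequent = 4, frequent = 8),
                            n_draws = 5,
                            statistic = function(e) mean(e$data), seed = 1)
  expect_equal(st2$mean_variance, 0)
  # below quota is an error here (the participant should not have passed)
  expect_error(
    sampling_stability(es2, quotas = c(infrequent = 6, frequent = 8),
                       n_draws = 3, statistic = function(e) mean(e$data)),
    "below quota")
  # variance shrinks as availability grows relative to the quota
  set.seed(4)
  base <- rnorm(64)
  mkv <- function(n) synthetic_epochs(
    data3d = array(rep(base, each = n) + rnorm(n * 64, sd = 0.5),
                   c(n, 1, 64)),
    conditions = "correct_response", halves = "H1")
  v_small <- sampling_stability(mkv(40), quotas = c(infrequent = 36,
                                                    frequent = 72),
                                n_draws = 8,
                                statistic = function(e) mean(e$data),
                                seed = 5)$mean_variance
  v_large <- sampling_stability(mkv(200), quotas = c(infrequent = 36,
                                                     frequent = 72),
                                n_draws = 8,
                                statistic = function(e) mean(e$data),
                                seed = 5)$mean_variance
  # finite-population sampling: a pool barely above quota varies less
  # across draws than a large pool, and both variances are tiny
  expect_lt(v_small, v_large)
  expect_lt(v_large, 0.001)
})

test_that("early/late split follows the median-onset tie rule", {
  es10 <- synthetic_epochs(data3d = array(0, c(10, 1, 64)),
                           onsets = sample(1:10))
  sp <- split_early_late(es10)
  expect_equal(n_epochs(sp$early), 5)
  expect_equal(n_epochs(sp$late), 5)
  es11 <- synthetic_epochs(data3d = array(0, c(11, 1, 64)),
                           onsets = sample(1:11))
  sp11 <- split_early_late(es11)
  expect_equal(n_epochs(sp11$early), 6)  # odd count: extra goes early
  expect_equal(n_epochs(sp11$late), 5)
  expect_lt(max(sp11$early$meta$onset_s), min(sp11$late$meta$onset_s))
  es1 <- synthetic_epochs(data3d = array(0, c(1, 1, 64)))
  expect_error(split_early_late(es1), "at least 2")
})
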