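#' Pipeline configuration
#'
#' Assembles every stage parameter of the end-to-end synthetic study into
#' one serializable list: group presets and sizes, protocol counts, the
#' preprocessing chain, epoch quotas, the TFR grid, and permutation
#' settings. Defaults run a small two-group demonstration (3 participants
#' per group, full 324-trial halves, a reduced 27 x 100 TFR grid and 400
#' permutations) in a few minutes; all sizes scale up or down through this
#' one object, and every random stage derives its seed from the single
#' top-level seed.
#'
#' @param participants_per_group Named vector, participants per group.
#' @param n_target_h1,n_nontarget_h1 H1 stimulus counts (H2 reverses them).
#' @param soa_s Trial period (s).
#' @param quotas Balanced epoch quotas, `c(infrequent =, frequent =)`.
#' @param behavior_models Per-group response models (see
#'   [simulate_behavior()]).
#' @param hp_hz,lp_hz Band-pass corners (Hz).
#' @param amp_threshold_uv,amp_channel_fraction Amplitude rejection rule.
#' @param blink_guard_s Blink rejection guard window (s around onset).
#' @param baseline_s Baseline interval (s).
#' @param f_min,f_max,n_freqs,n_times TFR grid.
#' @param itc_freq_hz ITC analysis frequency.
#' @param n_perm,itc_n_perm,alpha_levels Permutation settings.
#' @param age,gender Demographics used against the synthetic norm table.
#' @return A `tova_config` list.
#' @export
tova_config <- function(participants_per_group = c(control = 3, adhd = 3),
                        n_target_h1 = 72, n_nontarget_h1 = 252, soa_s = 2,
                        quotas = c(infrequent = 36, frequent = 72),
                        behavior_models = list(
                          control = list(p_hit = 0.97, p_commission = 0.05,
                                         rt_meanlog = log(0.38),
                                         rt_sdlog = 0.13,
                                         p_anticipatory = 0.005),
                          adhd = list(p_hit = 0.90, p_commission = 0.15,
                                      rt_meanlog = log(0.44),
                                      rt_sdlog = 0.22,
                                      p_anticipatory = 0.02)),
                        hp_hz = 2, lp_hz = 45,
                        amp_threshold_uv = 80, amp_channel_fraction = 0.5,
                        blink_guard_s = c(-0.4, 0.6),
                        baseline_s = c(-1, 0),
                        f_min = 4, f_max = 30, n_freqs = 27, n_times = 100,
                        itc_freq_hz = 10,
                        n_perm = 400, itc_n_perm = 200,
                        alpha_levels = c(0.05, 0.0005),
                        age = 30, gender = "female") {
  cfg <- as.list(environment())
  class(cfg) <- "tova_config"
  cfg
}

# deterministic per-stage seed derivation, kept well inside 32-bit range
derive_seed <- function(seed, k) as.integer((seed + 104729 * k) %% 2147483587L)

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

preprocess_participant <- function(rec, cfg) {
  rec <- filter_band(rec, cfg$hp_hz, cfg$lp_hz)
  rec <- rereference(rec)
  es <- epoch(rec)
  es <- reject_blink_epochs(es, rec$annotations, cfg$blink_guard_s)
  es <- reject_amplitude(es, cfg$amp_threshold_uv, cfg$amp_channel_fraction)
  baseline_correct(es, cfg$baseline_s)
}

#' Run the full synthetic study pipeline
#'
#' Simulates two participant groups through the complete analysis chain:
#' trial scheduling and behavior, EEG synthesis, band-pass filtering and
#' mastoid re-referencing, epoching with blink/amplitude rejection and
#' baseline correction, balanced epoch draws, behavioral standard scores,
#' windowed ERP group tests, intertrial coherence with permutation
#' significance, ERSP per group, Welch PSDs, and a permutation contrast of
#' group log spectral power. All artifacts are deterministic TSV/JSON files
#' derived from the single seed, so identical calls are byte-identical.
#'
#' @param config A [tova_config()] list.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config = tova_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "tova_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  groups <- names(cfg$participants_per_group)
  norms <- synthetic_norm_table()
  counter <- 0L
  balanced <- list()   # [[group]][[half]][[condition]] lists of epoch sets
  score_rows <- list()
  balance_rows <- list()
  stage_counts <- list()

  run_stage("simulate+preprocess", {
    for (g in groups) {
      for (p in seq_len(cfg$participants_per_group[[g]])) {
        pid <- sprintf("%s_%02d", g, p)
        halves <- list(
          H1 = c(cfg$n_target_h1, cfg$n_nontarget_h1),
          H2 = c(cfg$n_nontarget_h1, cfg$n_target_h1))
        ep_halves <- list()
        beh_all <- NULL
        for (h in names(halves)) {
          counter <- counter + 1L
          s <- derive_seed(seed, counter)
          sch <- make_schedule(h, halves[[h]][1], halves[[h]][2],
                               soa_s = cfg$soa_s, seed = s)
          beh <- simulate_behavior(sch, cfg$behavior_models[[g]],
                                   seed = s + 1L)
          params <- group_preset(g, seed = s + 2L)
          rec <- synthesize_eeg(sch, beh, params)
          ep_halves[[h]] <- preprocess_participant(rec, cfg)
          beh_all <- rbind(beh_all, as.data.frame(beh))
        }
        es <- bind_epochs(ep_halves)
        logs <- lapply(ep_halves, rejection_log)
        stage_counts[[pid]] <- do.call(rbind, Map(function(h, l) {
          l$half <- h; l$participant <- pid; l
        }, names(logs), logs))
        bal <- balance_epochs(es, cfg$quotas, seed = derive_seed(seed,
                                                                 counter + 500L))
        rep <- bal$report
        rep$participant <- pid
        balance_rows[[pid]] <- rep
        for (k in seq_len(nrow(rep))) {
          if (!rep$included[k]) next
          sel <- bal$epochs$meta$condition == rep$condition[k] &
            bal$epochs$meta$half == rep$half[k]
          cur <- tryCatch(balanced[[g]][[rep$half[k]]][[rep$condition[k]]],
                          error = function(e) NULL)
          balanced[[g]][[rep$half[k]]][[rep$condition[k]]] <-
            c(cur %||% list(), list(subset_epochs(bal$epochs, sel)))
        }
        raw <- raw_scores(beh_all)
        for (k in seq_len(nrow(raw))) {
          std <- standardize(raw[k, ], norms, cfg$age, cfg$gender)
          score_rows[[paste(pid, raw$half[k])]] <- cbind(
            data.frame(participant = pid, group = g,
                       stringsAsFactors = FALSE),
            raw[k, ], as.data.frame(t(std)),
            performance = classify_performance(std))
        }
      }
    }
  })

  run_stage("behavior-report", {
    scores <- do.call(rbind, score_rows)
    rownames(scores) <- NULL
    write_tsv(scores, file.path(out_dir, "behavior_scores.tsv"))
    write_tsv(do.call(rbind, balance_rows),
              file.path(out_dir, "balance_report.tsv"))
  })

  pool <- function(g, h, cond) {
    sets <- tryCatch(balanced[[g]][[h]][[cond]], error = function(e) NULL)
    if (is.null(sets)) NULL else bind_epochs(sets)
  }

  erp_tests <- NULL
  run_stage("erp", {
    rows <- list()
    for (h in c("H1", "H2")) {
      ga <- pool(groups[1], h, "correct_response")
      gb <- pool(groups[2], h, "correct_response")
      if (is.null(ga) || is.null(gb)) next
      for (roi in c("frontal", "parietal")) {
        tt <- window_amplitude_test(roi_signal(ga, roi), roi_signal(gb, roi),
                                    lock = "target")
        ra <- relock_to_response(ga)
        rb <- relock_to_response(gb)
        rr <- window_amplitude_test(roi_signal(ra, roi), roi_signal(rb, roi),
                                    lock = "response")
        tt$half <- h; tt$roi <- roi
        rr$half <- h; rr$roi <- roi
        rows <- c(rows, list(tt, rr))
      }
      erp_a <- grand_erp(roi_signal(ga, "parietal"))
      write_tsv(data.frame(time_s = attr(erp_a, "times_s"),
                           amplitude_uv = as.numeric(erp_a)),
                file.path(out_dir, sprintf("erp_grand_%s_%s.tsv",
                                           groups[1], h)))
    }
    if (length(rows)) {
      erp_tests <- do.call(rbind, rows)
      write_tsv(erp_tests, file.path(out_dir, "erp_window_tests.tsv"))
    }
  })

  grid <- build_freq_grid(cfg$f_min, cfg$f_max, cfg$n_freqs)
  itc_results <- list()
  run_stage("itc", {
    for (g in groups) {
      for (h in c("H1", "H2")) {
        es <- pool(g, h, "correct_response")
        if (is.null(es)) next
        counter <- counter + 1L
        x <- itc_significance(es, "parietal", cfg$itc_freq_hz,
                              n_times = cfg$n_times,
                              n_perm = cfg$itc_n_perm,
                              seed = derive_seed(seed, counter))
        itc_results[[paste(g, h)]] <- x
        write_itc_tsv(x, file.path(out_dir, sprintf("itc_%s_%s.tsv", g, h)))
      }
    }
  })

  perm_results <- list()
  run_stage("spectral+stats", {
    for (h in c("H1", "H2")) {
      for (cond in c("correct_response", "correct_inhibition")) {
        pa <- pool(groups[1], h, cond)
        pb <- pool(groups[2], h, cond)
        if (is.null(pa) || is.null(pb)) next
        rpa <- roi_tfr(pa, "parietal", grid, cfg$n_times)
        rpb <- roi_tfr(pb, "parietal", grid, cfg$n_times)
        write_tfr_tsv(ersp(rpa), file.path(out_dir, sprintf(
          "ersp_%s_%s_%s.tsv", groups[1], h, cond)))
        write_tfr_tsv(ersp(rpb), file.path(out_dir, sprintf(
          "ersp_%s_%s_%s.tsv", groups[2], h, cond)))
        counter <- counter + 1L
        pr <- permutation_ersp_diff(rpa, rpb, n_perm = cfg$n_perm,
                                    alpha = cfg$alpha_levels,
                                    seed = derive_seed(seed, counter))
        perm_results[[paste(h, cond)]] <- pr
        df <- data.frame(
          freq_hz = rep(pr$freqs_hz, times = length(pr$times_s)),
          time_s = rep(pr$times_s, each = length(pr$freqs_hz)),
          observed_db = as.vector(pr$observed_diff_db),
          p = as.vector(pr$p))
        for (a in names(pr$masks)) {
          df[[paste0("sig_", a)]] <- as.vector(pr$masks[[a]])
        }
        write_tsv(df, file.path(out_dir, sprintf("perm_%s_%s.tsv", h, cond)))
      }
    }
    for (g in groups) {
      es <- pool(g, "H1", "correct_response")
      if (is.null(es)) next
      pre <- welch_psd_epochs(es, "parietal", c(-1, 0), segment = "baseline")
      post <- welch_psd_epochs(es, "parietal", c(0, 1),
                               segment = "poststimulus")
      write_psd_tsv(pre, file.path(out_dir, sprintf("psd_%s_baseline.tsv", g)))
      write_psd_tsv(post, file.path(out_dir, sprintf("psd_%s_post.tsv", g)))
    }
  })

  manifest <- list(
    seed = seed,
    config = unclass(cfg),
    participants = lapply(stage_counts, function(df) {
      stats::setNames(as.list(df$n_out), paste(df$half, df$stage, sep = ":"))
    }),
    balance = lapply(balance_rows, function(df) {
      stats::setNames(as.list(df$drawn), paste(df$half, df$condition, sep = ":"))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, itc = itc_results,
                 permutation = perm_results, out_dir = out_dir))
}

#' Generate plain-text test fixtures
#'
#' Writes one or two small synthetic recordings (TSV + sidecars) with known
#' ground truth and an md5 checksum manifest, for integration tests and
#' external tooling. The `"small"` fixture injects a high-amplitude segment
#' and guarantees a blink so that every rejection branch is exercised.
#'
#' @param dir Output directory.
#' @param size `"tiny"` (8 trials, no artifacts) or `"small"` (16 trials
#'   with artifacts).
#' @param seed Integer seed.
#' @return Invisibly, a data.frame of files and checksums.
#' @export
make_fixtures <- function(dir, size = c("tiny", "small"), seed = 42) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_tr <- if (size == "tiny") c(3, 5) else c(6, 10)
  sch <- make_schedule("H1", n_tr[1], n_tr[2], seed = seed)
  beh <- simulate_behavior(sch, seed = seed + 1)
  params <- gen_params(seed = seed + 2,
                       blink_rate_per_min = if (size == "tiny") 0 else 6)
  rec <- synthesize_eeg(sch, beh, params)
  if (size == "small") {
    # inject one segment that trips the amplitude rule on most channels
    hit <- round((rec$events$onset_s[2] + 0.2) * rec$fs_hz)
    idx <- hit:(hit + round(0.1 * rec$fs_hz))
    eeg <- eeg_channels(rec$channel_labels)
    rec$data[eeg, idx] <- rec$data[eeg, idx] + 200
    # and guarantee at least one blink annotation over trial 4
    rec$annotations <- rbind(rec$annotations, data.frame(
      kind = "blink", start_s = rec$events$onset_s[4] + 0.1,
      end_s = rec$events$onset_s[4] + 0.4, stringsAsFactors = FALSE))
  }
  paths <- write_recording_tsv(rec, file.path(dir, paste0("fixture_", size)))
  sums <- tools::md5sum(unlist(paths))
  chk <- data.frame(file = basename(names(sums)), md5 = unname(sums),
                    stringsAsFactors = FALSE)
  write_tsv(chk, file.path(dir, paste0("fixture_", size, "_checksums.tsv")))
  invisible(chk)
}
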