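# which quota class a (condition, half) cell belongs to:
# infrequent = responses in H1, inhibitions in H2; frequent = the reverse.
quota_class <- function(condition, half) {
  infreq <- (half == "H1" & condition == "correct_response") |
    (half == "H2" & condition == "correct_inhibition")
  ifelse(infreq, "infrequent", "frequent")
}

#' Draw balanced epoch counts per condition
#'
#' Per (condition, half) cell, draws exactly the quota of epochs without
#' replacement when enough are available, otherwise marks the participant
#' excluded for that cell (exclusion is an outcome, not an error). Quotas
#' default to 36 for infrequent cells (responses in H1, inhibitions in H2)
#' and 72 for frequent cells, so a participant retained in both cells of a
#' half contributes 108 epochs. Only correct-response and correct-inhibition
#' epochs participate; error and invalid trials are ignored.
#'
#' @param epochs An `epoch_set`.
#' @param quotas Named vector `c(infrequent =, frequent =)`.
#' @param seed Integer seed; equal seeds reproduce the draw.
#' @return List with `epochs` (the drawn subset, chronological order) and
#'   `report` (per-cell data.frame: `condition`, `half`, `available`,
#'   `quota`, `drawn`, `included`) plus the seed.
#' @export
balance_epochs <- function(epochs, quotas = c(infrequent = 36, frequent = 72),
                           seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (any(quotas <= 0)) stopf("quotas must be positive")
  meta <- epochs$meta
  cells <- unique(meta[meta$condition %in%
                         c("correct_response", "correct_inhibition"),
                       c("condition", "half")])
  cells$condition <- as.character(cells$condition)
  cells$half <- as.character(cells$half)
  keep <- integer(0)
  report <- NULL
  draw <- with_seed(seed, {
    for (k in seq_len(nrow(cells))) {
      cond <- cells$condition[k]
      half <- cells$half[k]
      avail <- which(meta$condition == cond & meta$half == half)
      quota <- unname(quotas[quota_class(cond, half)])
      included <- length(avail) >= quota
      drawn <- if (included) sort(sample(avail, quota)) else integer(0)
      keep <- c(keep, drawn)
      report <- rbind(report, data.frame(
        condition = cond, half = half, available = length(avail),
        quota = quota, drawn = length(drawn), included = included,
        stringsAsFactors = FALSE))
    }
    list(keep = sort(keep), report = report)
  })
  out <- subset_epochs(epochs, draw$keep)
  out <- log_stage(out, "balance", n_epochs(epochs), length(draw$keep))
  list(epochs = out, report = draw$report, seed = seed)
}

#' Variance of a spectral statistic across repeated balanced draws
#'
#' Repeats [balance_epochs()] with distinct seeds and measures how much a
#' summary statistic (by default the mean parietal log-power from Welch PSD
#' of the poststimulus second) varies across draws, to check that balanced
#' subsampling does not bias spectral results.
#'
#' @param epochs An `epoch_set` that passes every quota it has trials for.
#' @param quotas As in [balance_epochs()].
#' @param n_draws Number of repeated draws.
#' @param statistic Function `epoch_set -> numeric vector`; `NULL` for the
#'   default ROI spectral power summary.
#' @param seed Base seed; draw i uses `seed + i - 1`.
#' @return List with `mean_variance` (mean across-statistic variance over
#'   draws) and `draws` (the per-draw statistic matrix).
#' @export
sampling_stability <- function(epochs, quotas = c(infrequent = 36,
                                                  frequent = 72),
                               n_draws = 11, statistic = NULL, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- epochs$meta
  cells <- unique(meta[meta$condition %in%
                         c("correct_response", "correct_inhibition"),
                       c("condition", "half")])
  for (k in seq_len(nrow(cells))) {
    avail <- sum(meta$condition == cells$condition[k] &
                   meta$half == cells$half[k])
    quota <- unname(quotas[quota_class(cells$condition[k], cells$half[k])])
    if (avail < quota) {
      stopf("cell %s/%s has %d epochs, below quota %d",
            cells$condition[k], cells$half[k], avail, quota)
    }
  }
  if (is.null(statistic)) {
    statistic <- function(es) {
      chans <- intersect(tova_rois()$parietal, es$channel_labels)
      if (length(chans) == 0L) chans <- eeg_channels(es$channel_labels)
      post <- c(0, min(1, es$time_s[length(es$time_s)] + 1 / es$fs_hz))
      psd <- welch_psd_epochs(es, channels = chans, interval_s = post,
                              segment = "poststimulus")
      mean(psd$log_power_db)
    }
  }
  vals <- lapply(seq_len(n_draws), function(i) {
    bal <- balance_epochs(epochs, quotas, seed = seed + i - 1)
    statistic(bal$epochs)
  })
  draws <- do.call(rbind, vals)
  list(mean_variance = mean(apply(draws, 2, stats::var)), draws = draws)
}

#' Split an epoch set into early and late halves
#'
#' Splits by median stimulus-onset time; with an odd count the extra trial
#' goes to the early subset.
#'
#' @param epochs An `epoch_set` with at least 2 trials.
#' @return List with `early` and `late` `epoch_set`s.
#' @export
split_early_late <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  if (n < 2L) stopf("need at least 2 epochs to split")
  ord <- order(epochs$meta$onset_s)
  n_early <- ceiling(n / 2)
  list(early = subset_epochs(epochs, ord[seq_len(n_early)]),
       late = subset_epochs(epochs, ord[(n_early + 1L):n]))
}
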