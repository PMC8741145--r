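#' Classify trials into TOVA response classes
#'
#' Targets with a valid response are correct responses; unanswered targets
#' are omissions; answered nontargets are commissions; unanswered
#' nontargets are correct inhibitions. Responses faster than the
#' anticipatory cutoff (150 ms from stimulus onset) are invalid and belong
#' to none of the four classes.
#'
#' @param record A `tova_behavior` data.frame (or any data.frame with
#'   `stim`, `responded`, `rt_s`).
#' @param anticipatory_cutoff_s Validity cutoff (s).
#' @return Factor with levels `correct_response`, `correct_inhibition`,
#'   `commission`, `omission`, `invalid`.
#' @export
classify_trials <- function(record, anticipatory_cutoff_s = 0.15) {
  stim <- as.character(record$stim)
  responded <- record$responded
  rt <- record$rt_s
  responded[is.na(responded)] <- FALSE
  cls <- ifelse(
    responded & !is.na(rt) & rt < anticipatory_cutoff_s, "invalid",
    ifelse(stim == "target",
           ifelse(responded, "correct_response", "omission"),
           ifelse(responded, "commission", "correct_inhibition")))
  factor(cls, levels = c("correct_response", "correct_inhibition",
                         "commission", "omission", "invalid"))
}

# z-difference d' with log-linear correction so 0/1 rates stay finite
dprime_zdiff <- function(hits, n_target, fa, n_nontarget) {
  h <- (hits + 0.5) / (n_target + 1)
  f <- (fa + 0.5) / (n_nontarget + 1)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Raw TOVA performance scores
#'
#' Per test half: mean and SD of correct-response RTs (ms), commission and
#' omission counts, and d-prime separating hit and false-alarm rates. The
#' default d-prime is the z-difference with log-linear correction; a
#' literal hit/false-alarm rate ratio is available as an alternative mode.
#' Anticipatory (invalid) responses are excluded from every class.
#'
#' @param record A `tova_behavior` data.frame.
#' @param anticipatory_cutoff_s Validity cutoff (s).
#' @param dprime_method `"zdiff"` (default) or `"ratio"`.
#' @return data.frame with one row per half: counts, `mean_rt_ms`,
#'   `rtv_ms`, `d_prime`. RT fields are NA (flagged by `rt_defined`) when
#'   fewer than 2 correct responses exist.
#' @export
raw_scores <- function(record, anticipatory_cutoff_s = 0.15,
                       dprime_method = c("zdiff", "ratio")) {
  dprime_method <- match.arg(dprime_method)
  cls <- classify_trials(record, anticipatory_cutoff_s)
  halves <- unique(as.character(record$half))
  rows <- lapply(halves, function(h) {
    in_h <- record$half == h
    k <- cls[in_h]
    rt <- record$rt_s[in_h]
    n_target <- sum(record$stim[in_h] == "target")
    n_nontarget <- sum(record$stim[in_h] == "nontarget")
    hits <- sum(k == "correct_response")
    fa <- sum(k == "commission")
    crt <- rt[k == "correct_response"]
    dp <- if (dprime_method == "zdiff") {
      dprime_zdiff(hits, n_target, fa, n_nontarget)
    } else {
      ((hits + 0.5) / (n_target + 1)) / ((fa + 0.5) / (n_nontarget + 1))
    }
    data.frame(
      half = h, n_target = n_target, n_nontarget = n_nontarget,
      n_correct_response = hits,
      n_correct_inhibition = sum(k == "correct_inhibition"),
      n_commission = fa, n_omission = sum(k == "omission"),
      n_invalid = sum(k == "invalid"),
      mean_rt_ms = if (length(crt) >= 1) 1000 * mean(crt) else NA_real_,
      rtv_ms = if (length(crt) >= 2) 1000 * stats::sd(crt) else NA_real_,
      d_prime = dp,
      rt_defined = length(crt) >= 2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tova_scores", "data.frame")
  out
}

# which direction of each raw measure means better performance
measure_direction <- function(measure) {
  worse_when_higher <- c("mean_rt_ms", "rtv_ms", "n_commission", "n_omission")
  ifelse(measure %in% worse_when_higher, -1, 1)
}

#' Norm-referenced standard scores
#'
#' Converts raw scores to the standard-score scale (mean 100, SD 15),
#' signed so that values below 100 always indicate worse performance than
#' the normative sample: error counts and RT measures enter with a negative
#' sign, d-prime with a positive one. `score = 100 + 15 * sign * (raw -
#' norm_mean) / norm_sd`; the transform is invertible given the norm row.
#'
#' @param raw One row of [raw_scores()] output (or a named list/row with
#'   the measure columns).
#' @param norms A [make_norm_table()] table.
#' @param age Participant age in years.
#' @param gender Gender label matching the table.
#' @param measures Raw measure columns to standardize.
#' @return Named numeric vector of standard scores (`std_<measure>`).
#' @export
standardize <- function(raw, norms, age, gender,
                        measures = c("mean_rt_ms", "rtv_ms", "n_commission",
                                     "n_omission", "d_prime")) {
  out <- numeric(0)
  for (m in measures) {
    val <- raw[[m]]
    if (is.null(val)) stopf("raw scores lack measure '%s'", m)
    cell <- norm_lookup(norms, m, age, gender)
    z <- (val - cell$mean) / cell$sd
    out[paste0("std_", m)] <- 100 + 15 * measure_direction(m) * z
  }
  out
}

#' Classify performance from standard scores
#'
#' Labels a score profile by its worst standard score using configurable
#' cutoffs. The default cutoffs (below 80: not within normal limits; 80 to
#' below 90: borderline; 90 and above: normal) are surrogate conventions,
#' not the proprietary vendor rules.
#'
#' @param std_scores Named numeric vector of standard scores.
#' @param thresholds Named vector `c(not_within = 80, borderline = 90)`;
#'   half-open intervals, lower bound inclusive.
#' @return One of `"not_within_normal"`, `"borderline"`, `"normal"`.
#' @export
classify_performance <- function(std_scores,
                                 thresholds = c(not_within = 80,
                                                borderline = 90)) {
  worst <- min(std_scores, na.rm = TRUE)
  if (worst < thresholds[["not_within"]]) "not_within_normal"
  else if (worst < thresholds[["borderline"]]) "borderline"
  else "normal"
}
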