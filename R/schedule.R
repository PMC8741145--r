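#' Build a TOVA trial schedule
#'
#' Generates one test half of the TOVA protocol: a randomized sequence of
#' target and nontarget stimuli at a constant stimulus-onset asynchrony.
#' In the standard protocol H1 presents 72 targets among 252 nontargets
#' (infrequent-target mode) and H2 reverses the counts; each 324-trial half
#' at a 2 s SOA lasts 648 s = 10.8 min.
#'
#' @param half `"H1"` or `"H2"` label carried into trial metadata.
#' @param n_target,n_nontarget Stimulus counts (non-negative integers).
#' @param soa_s Onset-to-onset trial period in seconds (stimulus duration is
#'   contained within it).
#' @param stim_duration_s Stimulus presentation time in seconds.
#' @param seed Optional integer seed for the stimulus order.
#' @return A `tova_schedule`: list with `trials` (data.frame `onset_s`,
#'   `stim`, `half`), `soa_s`, `stim_duration_s` and `duration_s`.
#' @export
#' @examples
#' sch <- make_schedule("H1", 72, 252, soa_s = 2, seed = 1)
#' sch$duration_s / 60  # 10.8 min
make_schedule <- function(half = c("H1", "H2"), n_target, n_nontarget,
                          soa_s = 2.0, stim_duration_s = 0.1, seed = NULL) {
  half <- match.arg(half)
  if (n_target < 0 || n_nontarget < 0) stopf("stimulus counts must be >= 0")
  if (soa_s <= 0) stopf("soa_s must be positive")
  if (stim_duration_s >= soa_s) stopf("stim_duration_s must be < soa_s")
  n <- as.integer(n_target + n_nontarget)
  stim <- rep(c("target", "nontarget"), c(n_target, n_nontarget))
  if (n > 1L) stim <- with_seed(seed, sample(stim))
  trials <- data.frame(
    trial = seq_len(n),
    onset_s = (seq_len(n) - 1) * soa_s,
    stim = factor(stim, levels = c("target", "nontarget")),
    half = rep(half, n),
    stringsAsFactors = FALSE
  )
  structure(
    list(trials = trials, soa_s = soa_s, stim_duration_s = stim_duration_s,
         duration_s = n * soa_s, half = half),
    class = "tova_schedule"
  )
}

#' @export
print.tova_schedule <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<tova_schedule> %s: %d trials (%d target, %d nontarget), SOA %.3g s, %.3g min\n",
              x$half, n, sum(x$trials$stim == "target"),
              sum(x$trials$stim == "nontarget"), x$soa_s, x$duration_s / 60))
  invisible(x)
}

#' Simulate button-press behavior on a trial schedule
#'
#' Draws per-trial responses from a simple observer model: targets are
#' answered with probability `p_hit`, nontargets with probability
#' `p_commission`; response times are lognormal; a small fraction of
#' responses are anticipatory (RT below the 150 ms validity cutoff).
#'
#' @param schedule A [make_schedule()] result.
#' @param model List with elements `p_hit`, `p_commission`, `rt_meanlog`,
#'   `rt_sdlog` (lognormal RT parameters, seconds) and `p_anticipatory`.
#' @param seed Optional integer seed.
#' @return A `tova_behavior` data.frame: one row per trial with `trial`,
#'   `onset_s`, `stim`, `half`, `responded`, `rt_s` (NA when no response).
#' @export
#' @examples
#' sch <- make_schedule("H1", 10, 30, seed = 1)
#' beh <- simulate_behavior(sch, seed = 2)
#' table(beh$stim, beh$responded)
simulate_behavior <- function(schedule,
                              model = list(p_hit = 0.95, p_commission = 0.1,
                                           rt_meanlog = log(0.4),
                                           rt_sdlog = 0.15,
                                           p_anticipatory = 0.01),
                              seed = NULL) {
  stopifnot(inherits(schedule, "tova_schedule"))
  m <- utils::modifyList(
    list(p_hit = 0.95, p_commission = 0.1, rt_meanlog = log(0.4),
         rt_sdlog = 0.15, p_anticipatory = 0.01),
    model
  )
  for (p in c("p_hit", "p_commission", "p_anticipatory")) {
    if (m[[p]] < 0 || m[[p]] > 1) stopf("%s must be in [0, 1]", p)
  }
  if (m$rt_sdlog <= 0) stopf("rt_sdlog must be > 0")
  tr <- schedule$trials
  n <- nrow(tr)
  out <- with_seed(seed, {
    p_resp <- ifelse(tr$stim == "target", m$p_hit, m$p_commission)
    responded <- stats::runif(n) < p_resp
    rt <- stats::rlnorm(n, m$rt_meanlog, m$rt_sdlog)
    anticipatory <- stats::runif(n) < m$p_anticipatory
    rt[anticipatory] <- stats::runif(sum(anticipatory), 0.03, 0.149)
    rt <- pmin(rt, schedule$soa_s * 0.99)  # responses land within the trial
    rt[!responded] <- NA_real_
    data.frame(tr, responded = responded, rt_s = rt,
               stringsAsFactors = FALSE)
  })
  class(out) <- c("tova_behavior", "data.frame")
  out
}
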