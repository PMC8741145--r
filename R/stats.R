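#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical distribution
#' functions; the p-value is asymptotic for large samples with the exact
#' small-sample computation where available.
#'
#' @param x,y Numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values; monotone non-decreasing in raw-p rank.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param alpha Rejection level applied to the adjusted values.
#' @return List with `p_adj` and logical `reject`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= alpha)
}

# accept roi_power or plain trials x freq x time array; return trials x K
flatten_power <- function(x) {
  if (inherits(x, "roi_power")) x <- x$power
  d <- dim(x)
  if (length(d) != 3) stopf("expected a trials x freq x time power array")
  list(mat = matrix(x, d[1]), nf = d[2], nt = d[3])
}

#' Permutation contrast of group log mean spectral power
#'
#' The observed statistic per (frequency, time) tile is the difference of
#' the groups' log mean power, in dB: `10 * (log10(mean A) - log10(mean
#' B))`. The null is built by permuting trial group labels; two-sided
#' permutation p-values use the absolute null with add-one correction,
#' `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`, and both significance
#' levels are evaluated against the same null so the stricter mask is
#' always nested inside the looser one. Null confidence bounds per tile
#' are also returned. Tests are uncorrected across tiles.
#'
#' @param power_a,power_b [roi_tfr()] results (or trials x freq x time
#'   arrays) for the two groups.
#' @param n_perm Number of permutations (>= 1/min(alpha) recommended; a
#'   warning is given otherwise).
#' @param alpha Significance levels; both masks are computed by default.
#' @param seed Integer seed; fixed seeds reproduce masks exactly.
#' @return A `perm_result`: `observed_diff_db` (freq x time), `p`
#'   (freq x time), `masks` (list per level), `ci` (per level `lo`/`hi`
#'   null quantile matrices), `n_perm`, `alpha_levels`, `seed`,
#'   `freqs_hz`, `times_s`, `n_trials`.
#' @export
permutation_ersp_diff <- function(power_a, power_b, n_perm = 2000,
                                  alpha = c(0.05, 0.0005), seed = NULL) {
  fa <- flatten_power(power_a)
  fb <- flatten_power(power_b)
  if (fa$nf != fb$nf || fa$nt != fb$nt) stopf("group grids differ")
  A <- fa$mat
  B <- fb$mat
  if (nrow(A) < 2 || nrow(B) < 2) stopf("each group needs >= 2 trials")
  if (n_perm < 1 / min(alpha)) {
    warning(sprintf("n_perm = %d is below 1/min(alpha) = %g; the strictest level is unreachable",
                    n_perm, 1 / min(alpha)), call. = FALSE)
  }
  K <- ncol(A)
  obs <- 10 * (log10(colMeans(A)) - log10(colMeans(B)))
  # canonical pooled order => swapping the input groups exactly negates the
  # null statistics, so masks are invariant under a label swap
  pooled <- rbind(A, B)
  lab <- rep(c(TRUE, FALSE), c(nrow(A), nrow(B)))
  canon <- order(rowMeans(pooled))
  pooled <- pooled[canon, , drop = FALSE]
  lab <- lab[canon]
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      pl <- sample(lab)
      10 * (log10(colMeans(pooled[pl, , drop = FALSE])) -
              log10(colMeans(pooled[!pl, , drop = FALSE])))
    }, numeric(K)))
  })
  cnt <- colSums(abs(null) >= matrix(abs(obs), n_perm, K, byrow = TRUE))
  pval <- (1 + cnt) / (n_perm + 1)
  shape <- function(v) matrix(v, fa$nf, fa$nt)
  masks <- ci <- list()
  for (a in alpha) {
    key <- format(a, scientific = FALSE)
    masks[[key]] <- shape(pval <= a)
    ci[[key]] <- list(
      lo = shape(apply(null, 2, stats::quantile, probs = a / 2)),
      hi = shape(apply(null, 2, stats::quantile, probs = 1 - a / 2)))
  }
  structure(
    list(observed_diff_db = shape(obs), p = shape(pval), masks = masks,
         ci = ci, n_perm = n_perm, alpha_levels = alpha, seed = seed,
         freqs_hz = if (inherits(power_a, "roi_power")) power_a$freqs_hz else NULL,
         times_s = if (inherits(power_a, "roi_power")) power_a$times_s else NULL,
         n_trials = c(a = nrow(A), b = nrow(B))),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  d <- dim(x$observed_diff_db)
  frac <- vapply(x$masks, mean, 0)
  cat(sprintf("<perm_result> %d x %d tiles, %d + %d trials, %d permutations\n",
              d[1], d[2], x$n_trials[1], x$n_trials[2], x$n_perm))
  for (k in names(frac)) {
    cat(sprintf("  alpha %s: %.1f%% of tiles significant\n", k, 100 * frac[k]))
  }
  invisible(x)
}

#' Permutation significance of intertrial coherence
#'
#' Builds a null ITC distribution by circularly time-shifting each trial's
#' phase series by an independent random offset (the same shift across
#' channels within a trial, preserving cross-channel structure) and marks
#' the latencies where the observed ITC exceeds the per-latency null
#' (1 - alpha) quantile.
#'
#' @inheritParams itc
#' @param n_perm Number of surrogate shifts.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return An `itc_series` with `sig_mask`, `alpha` and the per-latency
#'   null `threshold`.
#' @export
itc_significance <- function(epochs, channels = "parietal", freq_hz = 10,
                             cycles = NULL, n_times = 200, n_perm = 200,
                             alpha = 0.05, seed = NULL) {
  obs <- itc(epochs, channels, freq_hz, cycles, n_times, keep_phase = TRUE)
  units <- obs$phase
  ntr <- obs$n_trials
  ntime <- length(obs$times_s)
  nch <- length(units)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      sh <- sample.int(ntime, ntr, replace = TRUE) - 1L
      col_idx <- ((rep(sh, times = ntime) +
                     rep(seq_len(ntime) - 1L, each = ntr)) %% ntime) + 1L
      flat <- cbind(rep(seq_len(ntr), ntime), col_idx)
      acc <- numeric(ntime)
      for (ch in seq_len(nch)) {
        up <- matrix(units[[ch]][flat], ntr, ntime)
        acc <- acc + Mod(complex(real = .colMeans(Re(up), ntr, ntime),
                                 imaginary = .colMeans(Im(up), ntr, ntime)))
      }
      acc / nch
    }, numeric(ntime)))
  })
  thr <- apply(null, 2, stats::quantile, probs = 1 - alpha)
  obs$phase <- NULL
  obs$sig_mask <- obs$itc > thr
  obs$alpha <- alpha
  obs$threshold <- thr
  obs$n_perm <- n_perm
  obs$seed <- seed
  obs
}
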