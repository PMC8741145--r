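#' Build a normative lookup table for behavioral measures
#'
#' Validates a set of normative cells (mean and SD of a raw behavioral
#' measure per age range and gender) into a lookup structure used by
#' [standardize()]. Age ranges are half-open `[age_lo, age_hi)` and must not
#' overlap within a (measure, gender) cell.
#'
#' @param rows data.frame with columns `measure`, `age_lo`, `age_hi`,
#'   `gender`, `mean`, `sd`.
#' @return A `tova_norms` data.frame.
#' @export
make_norm_table <- function(rows) {
  need <- c("measure", "age_lo", "age_hi", "gender", "mean", "sd")
  missing <- setdiff(need, names(rows))
  if (length(missing)) stopf("norm table lacks column(s): %s",
                             paste(missing, collapse = ", "))
  if (any(rows$sd <= 0)) stopf("norm sd must be > 0")
  if (any(rows$age_hi <= rows$age_lo)) stopf("age_hi must exceed age_lo")
  for (key in split(rows, list(rows$measure, rows$gender), drop = TRUE)) {
    if (nrow(key) < 2L) next
    key <- key[order(key$age_lo), ]
    if (any(key$age_lo[-1] < key$age_hi[-nrow(key)])) {
      stopf("overlapping age ranges for measure '%s' gender '%s'",
            key$measure[1], key$gender[1])
    }
  }
  structure(as.data.frame(rows), class = c("tova_norms", "data.frame"))
}

#' Look up the normative cell for one measure
#'
#' @param norms A [make_norm_table()] result.
#' @param measure Measure name (e.g. `"mean_rt_ms"`).
#' @param age Age in years.
#' @param gender Gender label matching the table.
#' @return One-row data.frame with `mean` and `sd`.
#' @export
norm_lookup <- function(norms, measure, age, gender) {
  stopifnot(inherits(norms, "tova_norms"))
  hit <- norms$measure == measure & norms$gender == gender &
    norms$age_lo <= age & age < norms$age_hi
  if (!any(hit)) {
    stopf("no norm row for measure '%s', age %g, gender '%s'",
          measure, age, gender)
  }
  norms[which(hit)[1L], c("mean", "sd"), drop = FALSE]
}

#' Synthetic adult norm table
#'
#' A stand-in normative table with plausible adult values for the five TOVA
#' measures (one 18-60 age band, both genders). Entirely synthetic: it lets
#' the standardization machinery run end to end but carries no normative
#' authority. Raw units: RT measures in ms, error measures in counts per
#' half, d-prime dimensionless.
#'
#' @return A `tova_norms` table.
#' @export
synthetic_norm_table <- function() {
  measures <- c("mean_rt_ms", "rtv_ms", "n_commission", "n_omission", "d_prime")
  means <- c(400, 80, 8, 2, 4)
  sds <- c(60, 25, 5, 2.5, 1.2)
  rows <- expand.grid(measure = measures, gender = c("female", "male"),
                      stringsAsFactors = FALSE)
  rows$age_lo <- 18
  rows$age_hi <- 60
  rows$mean <- means[match(rows$measure, measures)]
  rows$sd <- sds[match(rows$measure, measures)]
  make_norm_table(rows)
}

#' Estimate a norm table from a simulated cohort
#'
#' Reduces per-participant raw scores (rows of [raw_scores()] output pooled
#' across participants) to normative mean/SD cells, e.g. to build synthetic
#' norms from a large simulated sample.
#'
#' @param scores data.frame of raw scores, one row per participant(-half).
#' @param age_range Length-2 numeric, the age band the cohort represents.
#' @param gender Gender label for the cells.
#' @param measures Which score columns become norm rows.
#' @return A `tova_norms` table.
#' @export
estimate_norms <- function(scores, age_range = c(18, 60), gender = "any",
                           measures = c("mean_rt_ms", "rtv_ms",
                                        "n_commission", "n_omission",
                                        "d_prime")) {
  measures <- intersect(measures, names(scores))
  if (!length(measures)) stopf("no score columns to summarize")
  rows <- do.call(rbind, lapply(measures, function(m) {
    x <- scores[[m]]
    x <- x[is.finite(x)]
    data.frame(measure = m, age_lo = age_range[1], age_hi = age_range[2],
               gender = gender, mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  make_norm_table(rows)
}
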