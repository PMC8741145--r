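# Plain-text serialization. Continuous recordings travel as a TSV data
# matrix plus a key=value sidecar; events, annotations and result tables as
# TSV. All writers are deterministic (no timestamps), so reruns under one
# seed are byte-identical.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read an event table
#'
#' Columns: `trial`, `onset_s`, `stim`, `half`, `responded`, `rt_s`.
#'
#' @param events data.frame of events.
#' @param path File path.
#' @return The path (writer) or the data.frame (reader).
#' @export
write_events_tsv <- function(events, path) write_tsv(events, path)

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read_tsv(path)
  ev$stim <- factor(ev$stim, levels = c("target", "nontarget"))
  ev
}

#' Write / read an annotation table (`kind`, `start_s`, `end_s`)
#' @param annotations data.frame of annotations.
#' @param path File path.
#' @return The path (writer) or the data.frame (reader).
#' @export
write_annotations_tsv <- function(annotations, path) {
  write_tsv(annotations, path)
}

#' @rdname write_annotations_tsv
#' @export
read_annotations_tsv <- function(path) read_tsv(path)

#' Write generator parameters as key=value lines
#'
#' Scalar and vector parameters are flattened (`key=v1,v2`); the ERP
#' component list is encoded one component per line. [read_gen_params()]
#' restores a `gen_params` object.
#'
#' @param params A `gen_params` list.
#' @param path File path.
#' @return The path.
#' @export
write_gen_params <- function(params, path) {
  lines <- character(0)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (nm == "erp_components") {
      for (cc in v) {
        lines <- c(lines, sprintf(
          "erp_component=%s,%.17g,%.17g,%.17g,%d", cc$label, cc$latency_s,
          cc$width_s, cc$amplitude_uv, as.integer(cc$sign)))
      }
    } else if (is.numeric(v) || is.character(v)) {
      lines <- c(lines, paste0(nm, "=", paste(format(v, digits = 17),
                                              collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gen_params
#' @export
read_gen_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  comps <- list()
  for (p in kv) {
    key <- p[[1]]
    val <- p[[2]]
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (key == "erp_component") {
      comps[[length(comps) + 1L]] <- list(
        label = parts[1], latency_s = as.numeric(parts[2]),
        width_s = as.numeric(parts[3]), amplitude_uv = as.numeric(parts[4]),
        sign = as.numeric(parts[5]))
    } else if (key == "channels") {
      args$channels <- parts
    } else {
      num <- suppressWarnings(as.numeric(parts))
      args[[key]] <- if (any(is.na(num))) parts else num
    }
  }
  if (length(comps)) args$erp_components <- comps
  do.call(gen_params, args)
}

#' Write / read a continuous recording as plain text
#'
#' Writes `<prefix>_data.tsv` (samples x channels), `<prefix>_events.tsv`,
#' `<prefix>_annotations.tsv` and `<prefix>_params.cfg`.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix for the four files.
#' @return Character vector of paths (writer) / the recording (reader).
#' @export
write_recording_tsv <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  paths <- paste0(prefix, c("_data.tsv", "_events.tsv", "_annotations.tsv",
                            "_params.cfg"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  write_tsv(df, paths[1])
  write_events_tsv(rec$events, paths[2])
  write_annotations_tsv(rec$annotations, paths[3])
  write_gen_params(rec$params, paths[4])
  invisible(paths)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(prefix) {
  data <- as.matrix(read_tsv(paste0(prefix, "_data.tsv")))
  params <- read_gen_params(paste0(prefix, "_params.cfg"))
  labels <- colnames(data)
  data <- t(data)
  rownames(data) <- labels
  structure(
    list(data = data, fs_hz = params$fs_hz, channel_labels = labels,
         events = read_events_tsv(paste0(prefix, "_events.tsv")),
         annotations = read_annotations_tsv(paste0(prefix,
                                                   "_annotations.tsv")),
         params = params),
    class = "eeg_recording"
  )
}

#' Write a TFR as a long-format table
#'
#' Columns `freq_hz`, `time_s`, `power_db`; kind, ROI, baseline and trial
#' count are written as `#`-prefixed header lines.
#'
#' @param tfr A `tfr_set`.
#' @param path File path.
#' @return The path.
#' @export
write_tfr_tsv <- function(tfr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s roi=%s n_trials=%d baseline=[%g,%g)",
                     tfr$kind, tfr$roi, tfr$n_trials,
                     tfr$baseline_interval_s[1], tfr$baseline_interval_s[2]),
             con)
  df <- data.frame(freq_hz = rep(tfr$freqs_hz, times = length(tfr$times_s)),
                   time_s = rep(tfr$times_s, each = length(tfr$freqs_hz)),
                   power_db = as.vector(tfr$power_db))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ITC time course
#' @param x An `itc_series`.
#' @param path File path.
#' @return The path.
#' @export
write_itc_tsv <- function(x, path) {
  df <- data.frame(time_s = x$times_s, itc = x$itc)
  if (!is.null(x$sig_mask)) df$significant <- x$sig_mask
  write_tsv(df, path)
}

#' Write a Welch PSD estimate
#' @param x A `psd_estimate`.
#' @param path File path.
#' @return The path.
#' @export
write_psd_tsv <- function(x, path) {
  write_tsv(data.frame(freq_hz = x$freqs_hz, log_power_db = x$log_power_db,
                       segment = x$segment), path)
}
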