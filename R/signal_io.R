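#' Construct a drinkometer volume trace
#'
#' A `volume_trace` holds a uniformly sampled cumulative consumed-volume signal
#' (ml) together with its sampling frequency and measurement identity. All
#' downstream processing (filtering, suck detection, interval extraction)
#' consumes this container, so device-specific readers only need to produce it.
#'
#' @param volume numeric vector of cumulative consumed volume in ml, one value
#'   per sample. Must be non-empty and finite.
#' @param fs sampling frequency in Hz (> 0). The suggested acquisition rate for
#'   the drinkometer is 1000 Hz.
#' @param measurement_id text label identifying the measurement, conventionally
#'   `"<participant>/<visit>"`.
#' @param t0 time of the first sample in seconds (default 0). Samples sit on
#'   the closed grid `t0 + (0:(n-1))/fs`.
#' @return an object of class `volume_trace`.
#' @examples
#' tr <- volume_trace(c(0, 0, 0.5), fs = 1000)
#' trace_times(tr)
#' @export
volume_trace <- function(volume, fs, measurement_id = "unknown", t0 = 0) {
  volume <- as.numeric(volume)
  if (length(volume) == 0L) {
    stop("data error: volume sequence is empty", call. = FALSE)
  }
  if (anyNA(volume) || any(!is.finite(volume))) {
    stop("data error: volume contains NA or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("sampling error: fs must be a single positive number", call. = FALSE)
  }
  structure(
    list(volume = volume, fs = as.numeric(fs),
         measurement_id = as.character(measurement_id), t0 = as.numeric(t0)),
    class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  n <- length(x$volume)
  cat(sprintf("<volume_trace> %s: %d samples @ %g Hz (%.1f s), %.2f -> %.2f ml\n",
              x$measurement_id, n, x$fs, (n - 1) / x$fs,
              x$volume[1], x$volume[n]))
  invisible(x)
}

#' Sample times of a volume trace
#'
#' @param trace a [volume_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$volume) - 1) / trace$fs
}

#' Measurement metadata and QC status
#'
#' @param participant participant label.
#' @param visit visit number (integer >= 1).
#' @param source_files character vector of the files the measurement came from.
#' @param qc_status one of `"included"`, `"excluded_interference"`,
#'   `"excluded_other"`.
#' @return an object of class `measurement_meta`.
#' @export
measurement_meta <- function(participant, visit = 1L,
                             source_files = character(),
                             qc_status = c("included", "excluded_interference",
                                           "excluded_other")) {
  qc_status <- match.arg(qc_status)
  visit <- as.integer(visit)
  if (is.na(visit) || visit < 1L) stop("visit must be an integer >= 1", call. = FALSE)
  structure(list(participant = as.character(participant), visit = visit,
                 source_files = as.character(source_files),
                 qc_status = qc_status),
            class = "measurement_meta")
}

#' Read a volume trace from the canonical CSV dialect
#'
#' The portable trace format is a UTF-8 comma-separated file with a header row
#' `time_s,volume_ml`, or `volume_ml` alone when `fs` is supplied explicitly.
#' When a time column is present the sampling frequency is inferred from the
#' median sample spacing and the grid is verified uniform to within 1 part in
#' 10^3.
#'
#' @param path path to the CSV file.
#' @param fs sampling frequency in Hz; required when the file has no `time_s`
#'   column, ignored otherwise.
#' @param measurement_id measurement label; defaults to the file name.
#' @return a [volume_trace()].
#' @export
read_trace_csv <- function(path, fs = NULL, measurement_id = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(measurement_id)) {
    measurement_id <- sub("\\.csv$", "", basename(path))
  }
  if (!"volume_ml" %in% names(df)) {
    stop("format error: missing column volume_ml in ", path, call. = FALSE)
  }
  vol <- df$volume_ml
  if (anyNA(vol)) stop("data error: NaN/NA volume values in ", path, call. = FALSE)
  if ("time_s" %in% names(df)) {
    tm <- df$time_s
    if (length(tm) < 2L) {
      if (is.null(fs)) stop("sampling error: cannot infer fs from a single sample",
                            call. = FALSE)
      return(volume_trace(vol, fs, measurement_id, t0 = tm[1]))
    }
    dt <- diff(tm)
    if (any(dt <= 0)) stop("sampling error: time_s not strictly increasing",
                           call. = FALSE)
    dt_med <- stats::median(dt)
    if (any(abs(dt - dt_med) > 1e-3 * dt_med)) {
      stop("sampling error: non-uniform sample spacing (beyond 1 part in 10^3)",
           call. = FALSE)
    }
    volume_trace(vol, fs = 1 / dt_med, measurement_id, t0 = tm[1])
  } else {
    if (is.null(fs)) {
      stop("format error: no time_s column and no fs given", call. = FALSE)
    }
    volume_trace(vol, fs, measurement_id, t0 = 0)
  }
}

#' Write a volume trace to the canonical CSV dialect
#'
#' @param trace a [volume_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace_times(trace), volume_ml = trace$volume)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Construct an interval table
#'
#' The unit of analysis for the burst-pause criterion: labelled inter-suck
#' interval candidates (pauses, in seconds) across measurements.
#'
#' @param participant character vector of participant labels.
#' @param visit integer vector of visit numbers.
#' @param interval_s numeric vector of pause durations in seconds (> 0, finite).
#' @return a `data.frame` with class `interval_table` and columns
#'   `participant`, `visit`, `interval_s`.
#' @export
interval_table <- function(participant = character(), visit = integer(),
                           interval_s = numeric()) {
  df <- data.frame(participant = as.character(participant),
                   visit = as.integer(visit),
                   interval_s = as.numeric(interval_s))
  validate_interval_table(df)
}

validate_interval_table <- function(df) {
  stopifnot(all(c("participant", "visit", "interval_s") %in% names(df)))
  if (nrow(df) > 0) {
    if (anyNA(df$interval_s) || any(!is.finite(df$interval_s))) {
      stop("data error: non-finite interval_s", call. = FALSE)
    }
    if (any(df$interval_s <= 0)) {
      stop("data error: interval_s must be strictly positive", call. = FALSE)
    }
  }
  class(df) <- unique(c("interval_table", class(df)))
  df
}

#' Write an interval table to CSV
#'
#' Writes the header `participant,visit,interval_s`; a read-back with
#' [read_interval_table()] reproduces the table to full stored precision.
#'
#' @param table an [interval_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(table, path) {
  table <- validate_interval_table(table)
  df <- data.frame(participant = table$participant, visit = table$visit,
                   interval_s = format(table$interval_s, digits = 17,
                                       scientific = FALSE, trim = TRUE))
  if (nrow(df) == 0) df <- df[0, , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read an interval table from CSV
#'
#' @param path path to a CSV with header `participant,visit,interval_s`.
#' @return an [interval_table()].
#' @export
read_interval_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(participant = "character"))
  need <- c("participant", "visit", "interval_s")
  if (!all(need %in% names(df))) {
    stop("format error: expected columns participant,visit,interval_s",
         call. = FALSE)
  }
  interval_table(df$participant, df$visit, df$interval_s)
}
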