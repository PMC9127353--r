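#' Detection settings for suck extraction
#'
#' Collects the thresholds of the suck-detection pipeline. The defaults are
#' the suggested operating values for a drinkometer sampling at 1000 Hz; they
#' are device-dependent (in particular `cutoff_hz` must lie above the spectral
#' band of a single suck and below the sensor noise band, and `min_amplitude`
#' depends on the signal-to-noise ratio).
#'
#' @param fs sampling frequency in Hz (default 1000).
#' @param cutoff_hz low-pass cutoff for volume filtering in Hz (default 0.5).
#' @param artifact_speed absolute speed above which a sample is treated as a
#'   measurement artifact, in ml/s (default 20).
#' @param min_amplitude minimal suck amplitude in ml/s (default 0.5); speed
#'   below this floor is treated as silence.
#' @param min_peak_distance_s minimal spacing between suck peaks in s
#'   (default 1), preventing noise from being detected as sucks.
#' @param min_suck_size_ml minimal suck size in ml (default 1); smaller
#'   detections are discarded as noise.
#' @param max_artifact_fraction QC threshold: fraction of artifact-repaired
#'   samples above which a measurement is excluded (default 0.01).
#' @param max_volume_decrease_ml QC threshold: tolerated decrease of the
#'   cumulative volume in ml (default 5).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(fs = 1000, cutoff_hz = 0.5, artifact_speed = 20,
                             min_amplitude = 0.5, min_peak_distance_s = 1,
                             min_suck_size_ml = 1,
                             max_artifact_fraction = 0.01,
                             max_volume_decrease_ml = 5) {
  vals <- c(fs = fs, cutoff_hz = cutoff_hz, artifact_speed = artifact_speed,
            min_amplitude = min_amplitude,
            min_peak_distance_s = min_peak_distance_s,
            min_suck_size_ml = min_suck_size_ml)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("detection_config: all settings must be positive and finite",
         call. = FALSE)
  }
  if (cutoff_hz >= fs / 2) {
    stop("detection_config: cutoff_hz must be below the Nyquist frequency",
         call. = FALSE)
  }
  structure(as.list(c(vals, max_artifact_fraction = max_artifact_fraction,
                      max_volume_decrease_ml = max_volume_decrease_ml)),
            class = "detection_config")
}

#' Zero-phase low-pass filter of a volume trace
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' (zero-phase, so suck timing is not shifted). The signal is padded with
#' replicated end values before filtering to suppress boundary transients.
#'
#' @param trace a [volume_trace()].
#' @param cfg a [detection_config()]; `cutoff_hz` is used.
#' @return a filtered [volume_trace()] of the same length.
#' @export
lowpass_filter <- function(trace, cfg = detection_config(fs = trace$fs)) {
  n <- length(trace$volume)
  warmup <- 24L
  if (n <= warmup) {
    stop("signal-too-short error: trace shorter than the filter warm-up (",
         warmup, " samples)", call. = FALSE)
  }
  npad <- min(n - 1L, ceiling(3 / cfg$cutoff_hz * trace$fs))
  padded <- c(rep(trace$volume[1], npad), trace$volume,
              rep(trace$volume[n], npad))
  out <- .butter4_filtfilt(padded, cfg$cutoff_hz, trace$fs)[npad + seq_len(n)]
  volume_trace(out, trace$fs, trace$measurement_id, trace$t0)
}

# 4th-order Butterworth low-pass as two cascaded biquad sections, each run
# forward-backward (zero phase). The cascade form stays numerically accurate
# at the very low normalized cutoffs used here (0.5 Hz at 1000 Hz), where a
# single 4th-order transfer function loses its unit DC gain to rounding.
# Each pass subtracts the signal's starting value first, so a signal entering
# flat (as the padded traces do) meets the filter at rest and leaves no
# start-up transient.
.butter4_filtfilt <- function(x, fc, fs) {
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0); sw <- sin(w0)
  one_pass <- function(b, a, x) {
    x0 <- x[1]
    as.numeric(signal::filter(b, a, x - x0)) + x0
  }
  for (q in 1 / (2 * sin(pi / 8 * c(1, 3)))) { # Butterworth pole Q factors
    alpha <- sw / (2 * q)
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2) / (1 + alpha)
    a <- c(1, -2 * cw / (1 + alpha), (1 - alpha) / (1 + alpha))
    x <- rev(one_pass(b, a, rev(one_pass(b, a, x))))
  }
  x
}

#' Differentiate a volume trace into a speed trace
#'
#' Central-difference derivative scaled to ml/s (one-sided differences at the
#' edges), preserving length and alignment with the parent trace.
#'
#' @param trace a [volume_trace()].
#' @return an object of class `speed_trace` with fields `speed` (ml/s),
#'   `fs`, `artifact_mask` (all `FALSE`), and the parent's identity.
#' @export
differentiate <- function(trace) {
  v <- trace$volume
  n <- length(v)
  if (n < 2L) {
    stop("signal-too-short error: need at least 2 samples to differentiate",
         call. = FALSE)
  }
  sp <- c(v[2] - v[1], (v[-(1:2)] - v[-((n - 1):n)]) / 2, v[n] - v[n - 1]) *
    trace$fs
  structure(list(speed = sp, fs = trace$fs,
                 artifact_mask = rep(FALSE, n),
                 measurement_id = trace$measurement_id, t0 = trace$t0),
            class = "speed_trace")
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("<speed_trace> %s: %d samples @ %g Hz, peak %.2f ml/s, %d artifact samples\n",
              x$measurement_id, length(x$speed), x$fs, max(abs(x$speed)),
              sum(x$artifact_mask)))
  invisible(x)
}

#' Delete and interpolate speed artifacts
#'
#' Every maximal run of samples whose absolute speed exceeds
#' `cfg$artifact_speed` is extended outward to the nearest flanking
#' zero-crossings of the speed signal and replaced by linear interpolation
#' between the flanking retained samples. Runs touching a signal edge are
#' replaced by the nearest retained value. Replaced samples are marked in
#' `artifact_mask`.
#'
#' @param speed a `speed_trace` (from [differentiate()]).
#' @param cfg a [detection_config()].
#' @return the repaired `speed_trace`; afterwards all `|speed|` are at or
#'   below `artifact_speed`.
#' @export
remove_artifacts <- function(speed, cfg = detection_config(fs = speed$fs)) {
  sp <- speed$speed
  n <- length(sp)
  bad <- abs(sp) > cfg$artifact_speed
  if (!any(bad)) return(speed)
  sgn <- sign(sp)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- rep(FALSE, n)
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    # extend to flanking zero-crossings (sample where speed is 0 or changes sign)
    while (a > 1L && sp[a - 1L] != 0 && sgn[a - 1L] == sgn[a]) a <- a - 1L
    while (b < n && sp[b + 1L] != 0 && sgn[b + 1L] == sgn[b]) b <- b + 1L
    mask[a:b] <- TRUE
  }
  out <- sp
  r2 <- rle(mask)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  for (i in which(r2$values)) {
    a <- starts2[i]; b <- ends2[i]
    left <- if (a > 1L) sp[a - 1L] else NA_real_
    right <- if (b < n) sp[b + 1L] else NA_real_
    if (is.na(left) && is.na(right)) {
      out[a:b] <- 0
    } else if (is.na(left)) {
      out[a:b] <- right
    } else if (is.na(right)) {
      out[a:b] <- left
    } else {
      out[a:b] <- left + (right - left) * seq_len(b - a + 1L) / (b - a + 2L)
    }
  }
  speed$speed <- out
  speed$artifact_mask <- speed$artifact_mask | mask
  speed
}

#' Floor sub-threshold speed to zero
#'
#' Samples with speed below `cfg$min_amplitude` are set to 0 (treated as
#' silence); all others are unchanged. The pre-floor signal is retained in the
#' `prefloor` field so that suck onsets/offsets can be located at true
#' zero-crossings rather than at the amplitude threshold.
#'
#' @param speed a `speed_trace` (artifact-repaired).
#' @param cfg a [detection_config()].
#' @return the floored `speed_trace`.
#' @export
floor_speed <- function(speed, cfg = detection_config(fs = speed$fs)) {
  speed$prefloor <- speed$speed
  speed$speed <- ifelse(speed$speed < cfg$min_amplitude, 0, speed$speed)
  speed
}

#' Detect sucks in a conditioned speed trace
#'
#' Candidate sucks are local maxima of the floored speed at or above
#' `min_amplitude`. Peaks closer together than `min_peak_distance_s` are
#' resolved greedily from the highest peak down, keeping the higher one. Each
#' suck's onset and offset are the nearest surrounding samples where the
#' repaired (pre-floor) speed returns to zero (within a small numerical
#' tolerance), and its size is the trapezoidal integral of the repaired speed
#' over `[onset, offset]`. Sucks smaller than `min_suck_size_ml` are
#' discarded; events sharing an onset (blended pulses under heavy filtering)
#' are deduplicated to the highest peak.
#'
#' @param speed a `speed_trace` after [remove_artifacts()] and
#'   [floor_speed()].
#' @param cfg a [detection_config()].
#' @return a `data.frame` of class `suck_events` with columns `onset_s`,
#'   `peak_s`, `offset_s`, `size_ml`, `peak_speed`, ordered by time. An empty
#'   frame is a valid result.
#' @export
detect_sucks <- function(speed, cfg = detection_config(fs = speed$fs)) {
  sp <- speed$speed
  raw <- if (!is.null(speed$prefloor)) speed$prefloor else speed$speed
  n <- length(sp)
  fs <- speed$fs
  empty <- data.frame(onset_s = numeric(), peak_s = numeric(),
                      offset_s = numeric(), size_ml = numeric(),
                      peak_speed = numeric())
  class(empty) <- c("suck_events", class(empty))
  if (n < 3L) return(empty)

  # strict-left / weak-right local maxima of the floored speed
  mid <- 2:(n - 1L)
  is_pk <- sp[mid] >= cfg$min_amplitude & sp[mid] > sp[mid - 1L] &
    sp[mid] >= sp[mid + 1L]
  peaks <- mid[is_pk]
  if (length(peaks) == 0L) return(empty)

  # greedy minimal peak spacing, highest first
  ord <- peaks[order(-sp[peaks], peaks)]
  min_gap <- cfg$min_peak_distance_s * fs
  kept <- integer(0)
  for (p in ord) {
    if (length(kept) == 0L || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  kept <- sort(kept)

  # onset/offset: nearest surrounding samples where the repaired speed is
  # (numerically) zero or negative
  ztol <- 1e-6
  at_zero <- raw <= ztol
  on_idx <- vapply(kept, function(p) {
    i <- p
    while (i > 1L && !at_zero[i]) i <- i - 1L
    i
  }, integer(1))
  off_idx <- vapply(kept, function(p) {
    i <- p
    while (i < n && !at_zero[i]) i <- i + 1L
    i
  }, integer(1))

  size <- vapply(seq_along(kept), function(j) {
    a <- on_idx[j]; b <- off_idx[j]
    s <- raw[a:b]
    sum((s[-1] + s[-length(s)]) / 2) / fs
  }, numeric(1))

  ev <- data.frame(onset_s = speed$t0 + (on_idx - 1L) / fs,
                   peak_s = speed$t0 + (kept - 1L) / fs,
                   offset_s = speed$t0 + (off_idx - 1L) / fs,
                   size_ml = size, peak_speed = sp[kept])
  ev <- ev[ev$size_ml >= cfg$min_suck_size_ml, , drop = FALSE]
  # deduplicate events sharing a span: keep the highest peak
  if (nrow(ev) > 1L) {
    key <- paste(ev$onset_s, ev$offset_s)
    keep <- unlist(lapply(split(seq_len(nrow(ev)), key), function(ix) {
      ix[which.max(ev$peak_speed[ix])]
    }), use.names = FALSE)
    ev <- ev[sort(keep), , drop = FALSE]
  }
  rownames(ev) <- NULL
  class(ev) <- c("suck_events", class(ev))
  ev
}

#' Extract inter-suck pauses from detected sucks
#'
#' One row per consecutive suck pair; the interval is the pause between
#' offset of suck *n* and onset of suck *n + 1*. Whether a pause is an
#' inter-suck or an inter-burst interval is decided later, from the pooled
#' interval distribution (see [derive_pc()]).
#'
#' @param sucks a `suck_events` frame, time-ordered.
#' @param meta a [measurement_meta()] supplying participant and visit labels.
#' @return an [interval_table()] with `nrow(sucks) - 1` rows (empty for fewer
#'   than two sucks).
#' @export
extract_intervals <- function(sucks, meta) {
  if (nrow(sucks) < 2L) return(interval_table())
  pauses <- sucks$onset_s[-1L] - sucks$offset_s[-nrow(sucks)]
  interval_table(participant = rep(meta$participant, length(pauses)),
                 visit = rep(meta$visit, length(pauses)),
                 interval_s = pauses)
}

#' Flag measurements with interference
#'
#' A measurement is excluded when the fraction of artifact-repaired samples
#' exceeds `cfg$max_artifact_fraction`, or when the cumulative volume drops by
#' more than `cfg$max_volume_decrease_ml` below its running maximum (a
#' physical impossibility for consumed volume, indicating sensor
#' interference).
#'
#' @param trace a raw [volume_trace()].
#' @param cfg a [detection_config()].
#' @param participant,visit labels for the returned metadata; parsed from
#'   `trace$measurement_id` (`"participant/visit"`) when omitted.
#' @return a [measurement_meta()] with `qc_status` set.
#' @export
qc_flag_interference <- function(trace, cfg = detection_config(fs = trace$fs),
                                 participant = NULL, visit = NULL) {
  if (is.null(participant) || is.null(visit)) {
    parts <- strsplit(trace$measurement_id, "/", fixed = TRUE)[[1]]
    if (is.null(participant)) participant <- parts[1]
    if (is.null(visit)) {
      visit <- if (length(parts) > 1L) suppressWarnings(as.integer(parts[2])) else 1L
      if (is.na(visit)) visit <- 1L
    }
  }
  sp <- remove_artifacts(differentiate(lowpass_filter(trace, cfg)), cfg)
  frac <- mean(sp$artifact_mask)
  drop_ml <- max(cummax(trace$volume) - trace$volume)
  status <- if (frac > cfg$max_artifact_fraction ||
                drop_ml > cfg$max_volume_decrease_ml) {
    "excluded_interference"
  } else {
    "included"
  }
  measurement_meta(participant, visit, source_files = trace$measurement_id,
                   qc_status = status)
}

#' Run the full suck-detection pipeline on a trace
#'
#' Fixed stage order: low-pass filter, differentiate, artifact repair,
#' amplitude floor, peak-based suck detection.
#'
#' @param trace a [volume_trace()].
#' @param cfg a [detection_config()].
#' @return a `suck_events` frame (see [detect_sucks()]).
#' @export
detect_pipeline <- function(trace, cfg = detection_config(fs = trace$fs)) {
  sp <- floor_speed(remove_artifacts(differentiate(lowpass_filter(trace, cfg)),
                                     cfg), cfg)
  detect_sucks(sp, cfg)
}
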