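#' Segment sucks into bursts under a pause criterion
#'
#' Greedy left-to-right segmentation: a new burst starts whenever the pause
#' between consecutive sucks (offset to onset) is at or above the criterion.
#' Every suck belongs to exactly one burst; within-burst pauses are all below
#' the criterion.
#'
#' @param sucks a `suck_events` frame, time-ordered.
#' @param pc a `pause_criterion` or a single positive number in seconds
#'   (`Inf` yields a single burst).
#' @return a `data.frame` with one row per burst: `burst`, `first_suck`,
#'   `last_suck` (row indices into `sucks`), `n_sucks`, `start_s`, `end_s`,
#'   `size_ml`.
#' @export
segment_bursts <- function(sucks, pc) {
  pc_s <- if (inherits(pc, "pause_criterion")) pc$pc_s else as.numeric(pc)
  if (is.na(pc_s) || pc_s <= 0) stop("pc must be > 0", call. = FALSE)
  n <- nrow(sucks)
  if (n == 0L) {
    return(data.frame(burst = integer(), first_suck = integer(),
                      last_suck = integer(), n_sucks = integer(),
                      start_s = numeric(), end_s = numeric(),
                      size_ml = numeric()))
  }
  pauses <- if (n > 1L) sucks$onset_s[-1L] - sucks$offset_s[-n] else numeric(0)
  burst_id <- cumsum(c(1L, as.integer(pauses >= pc_s)))
  first <- match(unique(burst_id), burst_id)
  last <- n + 1L - match(unique(burst_id), rev(burst_id))
  data.frame(burst = unique(burst_id),
             first_suck = first, last_suck = last,
             n_sucks = last - first + 1L,
             start_s = sucks$onset_s[first],
             end_s = sucks$offset_s[last],
             size_ml = vapply(seq_along(first), function(i) {
               sum(sucks$size_ml[first[i]:last[i]])
             }, numeric(1)))
}

#' Per-measurement macro- and microstructural parameter table
#'
#' One row per measurement. PC-independent columns describe the sucks
#' themselves and are identical under any criterion (`n_sucks`,
#' `total_volume_ml`, `meal_duration_s`, `mean_suck_size_ml`, `mean_ISI_s`
#' where the mean ISI uses only within-burst pauses, i.e. pauses below the
#' criterion); PC-dependent columns describe the bursts (`n_bursts`,
#' `mean_sucks_per_burst`, `mean_burst_size_ml`, `mean_burst_duration_s`,
#' `mean_IBI_s`). Undefined means are `NA`, never 0: `mean_IBI_s` requires at
#' least two bursts, and a measurement without sucks has every mean missing.
#'
#' @param measurements list of measurements, each a list with elements
#'   `sucks` (a `suck_events` frame) and `meta` (a [measurement_meta()]).
#' @param pc a `pause_criterion` or a positive number in seconds.
#' @return a `data.frame` with one row per measurement.
#' @export
build_parameter_table <- function(measurements, pc) {
  pc_s <- if (inherits(pc, "pause_criterion")) pc$pc_s else as.numeric(pc)
  rows <- lapply(measurements, function(m) {
    sucks <- m$sucks
    meta <- m$meta
    n <- nrow(sucks)
    base <- data.frame(participant = meta$participant, visit = meta$visit,
                       pc_s = pc_s, n_sucks = n)
    if (n == 0L) {
      return(cbind(base, data.frame(
        total_volume_ml = 0, meal_duration_s = NA_real_,
        mean_suck_size_ml = NA_real_, mean_ISI_s = NA_real_,
        n_bursts = 0L, mean_sucks_per_burst = NA_real_,
        mean_burst_size_ml = NA_real_, mean_burst_duration_s = NA_real_,
        mean_IBI_s = NA_real_)))
    }
    pauses <- if (n > 1L) sucks$onset_s[-1L] - sucks$offset_s[-n] else numeric(0)
    isis <- pauses[pauses < pc_s]
    ibis <- pauses[pauses >= pc_s]
    bursts <- segment_bursts(sucks, pc_s)
    cbind(base, data.frame(
      total_volume_ml = sum(sucks$size_ml),
      meal_duration_s = sucks$offset_s[n] - sucks$onset_s[1],
      mean_suck_size_ml = mean(sucks$size_ml),
      mean_ISI_s = if (length(isis)) mean(isis) else NA_real_,
      n_bursts = nrow(bursts),
      mean_sucks_per_burst = mean(bursts$n_sucks),
      mean_burst_size_ml = mean(bursts$size_ml),
      mean_burst_duration_s = mean(bursts$end_s - bursts$start_s),
      mean_IBI_s = if (nrow(bursts) >= 2L) mean(ibis) else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
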