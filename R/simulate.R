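#' Simulator configuration
#'
#' Parameters of the synthetic drinkometer generator. Pauses are drawn from a
#' two-component lognormal mixture whose log-domain modes default to the
#' canonical values observed for pooled human drinkometer recordings
#' (inter-suck intervals peaking at `exp(-0.0325) ~ 0.97 s`, inter-burst
#' intervals at `exp(1.1460) ~ 3.15 s`). Sucks are rendered as raised-cosine
#' speed pulses. The default device profile is a brisk-sucking one (0.5 s
#' pulses, low sensor noise); see [sim_detection_config()] for detection
#' settings matched to it.
#'
#' @param seed integer seed.
#' @param fs sampling frequency in Hz.
#' @param n_bursts number of bursts per simulated meal.
#' @param sucks_per_burst_mean mean sucks per burst (geometric distribution
#'   on 1, 2, ...).
#' @param isi_logmean,isi_logsd log_e-domain mean and sd of within-burst
#'   pauses.
#' @param ibi_logmean,ibi_logsd log_e-domain mean and sd of between-burst
#'   pauses. Requires `isi_logmean < ibi_logmean`.
#' @param mix_weight_isi fraction of pauses that are ISIs when generating
#'   pure interval samples (0 < w < 1).
#' @param suck_size_mean_ml,suck_size_sd_ml suck size distribution in ml
#'   (normal, truncated below at 20% of the mean).
#' @param suck_duration_s duration of the raised-cosine suck pulse in s.
#' @param noise_sd_ml additive Gaussian volume noise per sample in ml.
#' @param artifact_rate_per_min expected artifact spikes per minute (Poisson).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, fs = 1000, n_bursts = 12,
                       sucks_per_burst_mean = 3.5,
                       isi_logmean = -0.0325, isi_logsd = 0.45,
                       ibi_logmean = 1.1460, ibi_logsd = 0.55,
                       mix_weight_isi = 0.70,
                       suck_size_mean_ml = 2, suck_size_sd_ml = 0.5,
                       suck_duration_s = 0.5,
                       noise_sd_ml = 0.02, artifact_rate_per_min = 0) {
  if (!(mix_weight_isi > 0 && mix_weight_isi < 1)) {
    stop("mix_weight_isi must be in (0, 1)", call. = FALSE)
  }
  if (!(isi_logmean < ibi_logmean)) {
    stop("isi_logmean must be below ibi_logmean", call. = FALSE)
  }
  scales <- c(fs = fs, n_bursts = n_bursts,
              sucks_per_burst_mean = sucks_per_burst_mean,
              isi_logsd = isi_logsd, ibi_logsd = ibi_logsd,
              suck_size_mean_ml = suck_size_mean_ml,
              suck_duration_s = suck_duration_s)
  if (any(scales <= 0)) stop("scale parameters must be > 0", call. = FALSE)
  if (sucks_per_burst_mean < 1) {
    stop("sucks_per_burst_mean must be >= 1", call. = FALSE)
  }
  if (exp(isi_logmean) <= suck_duration_s) {
    stop("config error: the modal within-burst pause (exp(isi_logmean)) must ",
         "exceed suck_duration_s", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), fs = fs, n_bursts = n_bursts,
                 sucks_per_burst_mean = sucks_per_burst_mean,
                 isi_logmean = isi_logmean, isi_logsd = isi_logsd,
                 ibi_logmean = ibi_logmean, ibi_logsd = ibi_logsd,
                 mix_weight_isi = mix_weight_isi,
                 suck_size_mean_ml = suck_size_mean_ml,
                 suck_size_sd_ml = suck_size_sd_ml,
                 suck_duration_s = suck_duration_s,
                 noise_sd_ml = noise_sd_ml,
                 artifact_rate_per_min = artifact_rate_per_min),
            class = "sim_config")
}

#' Detection settings matched to a simulator configuration
#'
#' The simulated raised-cosine suck pulse of duration `W` has a single
#' spectral line at `1/W` Hz; the low-pass cutoff is placed at `5/W` so the
#' pulse passes with negligible edge distortion (keeping onset/offset timing
#' at sample accuracy) while broadband sensor noise is removed, and the
#' minimal peak spacing is set to `W` (two distinct pulses can peak no closer
#' than one pulse width apart). The remaining thresholds keep their suggested
#' defaults.
#'
#' @param cfg a [sim_config()].
#' @return a [detection_config()].
#' @export
sim_detection_config <- function(cfg) {
  detection_config(fs = cfg$fs, cutoff_hz = 5 / cfg$suck_duration_s,
                   min_peak_distance_s = cfg$suck_duration_s)
}

#' Analytic criterion of the generating mixture
#'
#' The ground-truth burst-pause criterion of a simulator configuration: the
#' crossing point of the two weighted generating log-domain Gaussian
#' densities, computed with the same closed form as
#' [component_intersection()].
#'
#' @param cfg a [sim_config()].
#' @return the crossing point in the log_e domain.
#' @export
true_intersection <- function(cfg) {
  component_intersection(cfg$mix_weight_isi, cfg$isi_logmean, cfg$isi_logsd,
                         1 - cfg$mix_weight_isi, cfg$ibi_logmean,
                         cfg$ibi_logsd)
}

#' Simulate a pure interval sample
#'
#' Draws `n` pauses from the two-component lognormal mixture: with
#' probability `mix_weight_isi` an ISI (lognormal with log-mean
#' `isi_logmean`), otherwise an IBI. Deterministic under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param n number of intervals (>= 1).
#' @param participant,visit labels for the returned table.
#' @return list with `table` (an [interval_table()]) and `truth` (list with
#'   `labels` — `"ISI"`/`"IBI"` per row — and `pc_log`, the analytic crossing
#'   of the generating components).
#' @export
simulate_intervals <- function(cfg, n, participant = "sim", visit = 1L) {
  stopifnot(n >= 1)
  with_seed(cfg$seed, {
    is_isi <- stats::runif(n) < cfg$mix_weight_isi
    vals <- ifelse(is_isi,
                   stats::rlnorm(n, cfg$isi_logmean, cfg$isi_logsd),
                   stats::rlnorm(n, cfg$ibi_logmean, cfg$ibi_logsd))
    list(table = interval_table(rep(participant, n), rep(visit, n), vals),
         truth = list(labels = ifelse(is_isi, "ISI", "IBI"),
                      pc_log = tryCatch(true_intersection(cfg),
                                        error = function(e) NA_real_)))
  })
}

# raised-cosine speed pulse of given duration and area (= suck size); the
# pulse's implicit zero endpoints sit exactly duration_s apart
.suck_pulse <- function(duration_s, size_ml, fs) {
  n <- max(3L, round(duration_s * fs) - 1L)
  t <- seq_len(n) / (n + 1)
  p <- 1 - cos(2 * pi * t)
  p * size_ml * fs / sum(p) # normalize so sum(p)/fs == size
}

#' Simulate a drinkometer volume trace with ground truth
#'
#' Renders a meal as `n_bursts` bursts of raised-cosine suck pulses. Pauses
#' between sucks within a burst are drawn from the ISI distribution, pauses
#' between bursts from the IBI distribution; suck sizes are truncated-normal.
#' The cumulative volume is the integral of the rendered speed plus Gaussian
#' sensor noise; optional artifact spikes (speed excursions beyond the usual
#' artifact threshold) are injected at Poisson times. The noiseless,
#' artifact-free volume is non-decreasing by construction.
#'
#' @param cfg a [sim_config()].
#' @param measurement_id label for the trace.
#' @return list with `trace` (a [volume_trace()]) and `truth`: data frame
#'   `sucks` (`onset_s`, `offset_s`, `size_ml`), data frame `pauses`
#'   (`interval_s`, `label`), `n_bursts`, `pc_log` (analytic crossing, `NA`
#'   when undefined), and `artifact_times_s`.
#' @export
simulate_trace <- function(cfg, measurement_id = "sim/1") {
  with_seed(cfg$seed, {
    n_sucks_per_burst <- 1L + stats::rgeom(cfg$n_bursts,
                                           prob = 1 / cfg$sucks_per_burst_mean)
    n_sucks <- sum(n_sucks_per_burst)
    sizes <- stats::rnorm(n_sucks, cfg$suck_size_mean_ml, cfg$suck_size_sd_ml)
    sizes <- pmax(sizes, 0.2 * cfg$suck_size_mean_ml)

    # pause sequence between consecutive sucks: ISI within a burst, IBI between
    labels <- character(0)
    for (b in seq_len(cfg$n_bursts)) {
      if (n_sucks_per_burst[b] > 1L) {
        labels <- c(labels, rep("ISI", n_sucks_per_burst[b] - 1L))
      }
      if (b < cfg$n_bursts) labels <- c(labels, "IBI")
    }
    pauses <- ifelse(labels == "ISI",
                     stats::rlnorm(length(labels), cfg$isi_logmean,
                                   cfg$isi_logsd),
                     stats::rlnorm(length(labels), cfg$ibi_logmean,
                                   cfg$ibi_logsd))

    lead <- 3
    onsets <- lead + c(0, cumsum(pauses + cfg$suck_duration_s))
    total_s <- onsets[n_sucks] + cfg$suck_duration_s + lead
    n <- ceiling(total_s * cfg$fs)
    speed <- numeric(n)
    shape <- .suck_pulse(cfg$suck_duration_s, 1, cfg$fs)
    for (i in seq_len(n_sucks)) {
      idx <- round(onsets[i] * cfg$fs) + seq_along(shape)
      speed[idx] <- speed[idx] + shape * sizes[i]
    }
    volume <- cumsum(speed) / cfg$fs

    artifact_times <- numeric(0)
    if (cfg$artifact_rate_per_min > 0) {
      n_art <- stats::rpois(1, cfg$artifact_rate_per_min * total_s / 60)
      if (n_art > 0) {
        artifact_times <- sort(stats::runif(n_art, 1, total_s - 1))
        # transient sensor interference: a 10 ml excursion with steep edges,
        # producing speed spikes far beyond any physiological suck
        blip <- c(seq(0, 10, length.out = round(0.01 * cfg$fs)),
                  rep(10, round(0.08 * cfg$fs)),
                  seq(10, 0, length.out = round(0.01 * cfg$fs)))
        for (at in artifact_times) {
          idx <- round(at * cfg$fs) + seq_along(blip)
          idx <- idx[idx <= n]
          volume[idx] <- volume[idx] + blip[seq_along(idx)]
        }
      }
    }
    if (cfg$noise_sd_ml > 0) {
      volume <- volume + stats::rnorm(n, 0, cfg$noise_sd_ml)
    }

    truth <- list(
      sucks = data.frame(onset_s = onsets,
                         offset_s = onsets + cfg$suck_duration_s,
                         size_ml = sizes),
      pauses = data.frame(interval_s = pauses, label = labels),
      n_bursts = cfg$n_bursts,
      pc_log = tryCatch(true_intersection(cfg), error = function(e) NA_real_),
      artifact_times_s = artifact_times)
    list(trace = volume_trace(volume, cfg$fs, measurement_id), truth = truth)
  })
}
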