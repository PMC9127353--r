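test_that("low-pass filter passes DC and the pass band, kills the stop band", {
  fs <- 1000
  cfg <- detection_config(fs = fs)

  const <- volume_trace(rep(5, 2000), fs)
  expect_equal(lowpass_filter(const, cfg)$volume, rep(5, 2000),
               tolerance = 1e-9)

  # amplitude transfer measured by sinusoid regression on the middle section
  measure_gain <- function(freq, dur = 60) {
    t <- seq(0, dur, by = 1 / fs)
    tr <- volume_trace(10 + sin(2 * pi * freq * t), fs)
    out <- lowpass_filter(tr, cfg)$volume
    mid <- t > dur / 4 & t < 3 * dur / 4
    co <- coef(lm(out[mid] ~ sin(2 * pi * freq * t[mid]) +
                    cos(2 * pi * freq * t[mid])))
    sqrt(co[2]^2 + co[3]^2)
  }
  expect_gt(measure_gain(0.1), 0.99)      # 0.1 Hz within 1%
  expect_lt(measure_gain(5), 0.1)         # 5 Hz attenuated >= 20 dB

  expect_error(lowpass_filter(volume_trace(1:5, fs), cfg),
               "signal-too-short")
})

test_that("differentiation recovers analytic derivatives", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  ramp <- differentiate(volume_trace(t, fs)) # 1 ml/s ramp
  expect_equal(ramp$speed, rep(1, length(t)), tolerance = 1e-9)

  flat <- differentiate(volume_trace(rep(3, 100), fs))
  expect_equal(flat$speed, rep(0, 100))
  expect_false(any(flat$artifact_mask))

  t1 <- seq(0, 1, by = 1 / fs)
  quad <- differentiate(volume_trace(t1^2, fs))
  expect_lt(max(abs(quad$speed - 2 * t1)), 10 / fs)

  expect_error(differentiate(volume_trace(1, fs)), "signal-too-short")
})

test_that("artifact runs are deleted and linearly interpolated", {
  fs <- 100
  cfg <- detection_config(fs = fs)

  clean <- as_speed_trace(runif(50, 0, 10), fs)
  out <- remove_artifacts(clean, cfg)
  expect_equal(out$speed, clean$speed)
  expect_false(any(out$artifact_mask))

  spike <- as_speed_trace(c(0, 0, 50, 0, 0), fs)
  rep1 <- remove_artifacts(spike, cfg)
  expect_equal(rep1$speed, rep(0, 5))
  expect_equal(rep1$artifact_mask, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(abs(rep1$speed) <= cfg$artifact_speed))

  two <- as_speed_trace(c(1, 0, 40, 0, 1, 0, -35, 0, 1), fs)
  rep2 <- remove_artifacts(two, cfg)
  runs <- rle(rep2$artifact_mask)
  expect_equal(sum(runs$values), 2L)
  expect_true(all(abs(rep2$speed) <= cfg$artifact_speed))
})

test_that("artifact runs extend to flanking zero-crossings before repair", {
  fs <- 100
  cfg <- detection_config(fs = fs)
  # spike riding on a positive lobe: the whole lobe goes, flanked by zeros
  sp <- as_speed_trace(c(0, 2, 5, 30, 5, 2, 0, 1), fs)
  out <- remove_artifacts(sp, cfg)
  expect_equal(out$artifact_mask,
               c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # linear interpolation between the flanking zeros
  expect_equal(out$speed, c(0, 0, 0, 0, 0, 0, 0, 1))
})

test_that("speed flooring zeroes sub-threshold samples only", {
  fs <- 10
  cfg <- detection_config(fs = fs)
  sp <- as_speed_trace(c(0.2, 0.6, 0.4, 1.0), fs)
  expect_equal(floor_speed(sp, cfg)$speed, c(0, 0.6, 0, 1.0))
  hi <- as_speed_trace(c(0.5, 0.8, 2), fs)
  expect_equal(floor_speed(hi, cfg)$speed, c(0.5, 0.8, 2))
  lo <- as_speed_trace(c(0.1, 0.2, 0.3), fs)
  floored <- floor_speed(lo, cfg)
  expect_equal(floored$speed, c(0, 0, 0))
  expect_equal(nrow(detect_sucks(floored, cfg)), 0L)
})

test_that("suck detection recovers pulse trains with correct sizes", {
  fs <- 1000
  cfg <- detection_config(fs = fs)
  # 5 raised-cosine pulses, amplitude 4 ml/s, width 1 s -> area 2 ml each
  onsets <- 2 + (0:4) * 3
  sp <- as_speed_trace(make_speed(onsets, 4, 1, fs, 18), fs)
  ev <- detect_sucks(floor_speed(sp, cfg), cfg)
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$size_ml, rep(2, 5), tolerance = 0.01)
  expect_equal(ev$onset_s, onsets, tolerance = 2 / fs)
  expect_equal(ev$peak_s, onsets + 0.5, tolerance = 2 / fs)

  # area 0.8 ml pulse is below the 1 ml suck-size floor
  small <- as_speed_trace(make_speed(2, 1.6, 1, fs, 6), fs)
  expect_equal(nrow(detect_sucks(floor_speed(small, cfg), cfg)), 0L)

  # two pulses peaking 0.4 s apart violate the 1 s peak spacing: one survives
  close <- as_speed_trace(make_speed(c(2, 2.4), 10, 0.3, fs, 6), fs)
  expect_equal(nrow(detect_sucks(floor_speed(close, cfg), cfg)), 1L)
})

test_that("interval extraction takes offset-to-onset pauses", {
  sucks <- data.frame(onset_s = c(0, 1.5, 5.0), peak_s = c(0.2, 1.7, 5.2),
                      offset_s = c(0.5, 2.0, 5.5), size_ml = c(2, 2, 2),
                      peak_speed = c(4, 4, 4))
  meta <- measurement_meta("P01", 2)
  tab <- extract_intervals(sucks, meta)
  expect_equal(tab$interval_s, c(1, 3))
  expect_equal(unique(tab$participant), "P01")
  expect_equal(unique(tab$visit), 2L)
  expect_equal(nrow(extract_intervals(sucks[1, ], meta)), 0L)
})

test_that("interference QC flags artifacts and volume decreases", {
  fs <- 1000
  cfg <- detection_config(fs = fs, cutoff_hz = 50)
  t <- seq(0, 30, by = 1 / fs)

  clean <- volume_trace(5 * t / max(t), fs, "p/1")
  expect_equal(qc_flag_interference(clean, cfg)$qc_status, "included")

  drop <- 5 * t / max(t)
  drop[t > 20] <- drop[t > 20] - 10 # 10 ml downward step
  expect_equal(qc_flag_interference(volume_trace(drop, fs, "p/1"), cfg)$qc_status,
               "excluded_interference")

  # repeated large jumps: enough repaired samples to exceed the 1% budget
  jumpy <- 5 * t / max(t)
  for (at in seq(2, 28, by = 2)) {
    jumpy[t >= at] <- jumpy[t >= at] + 2
  }
  expect_equal(qc_flag_interference(volume_trace(jumpy, fs, "p/1"), cfg)$qc_status,
               "excluded_interference")
})

test_that("detection respects conservation and offset invariance", {
  cfg <- sim_detection_config(sim_config())
  sim <- simulate_trace(sim_config(seed = 30, n_bursts = 8, noise_sd_ml = 0))
  filtered <- lowpass_filter(sim$trace, cfg)
  sucks <- detect_pipeline(sim$trace, cfg)
  total <- diff(range(filtered$volume))
  expect_lte(sum(sucks$size_ml), total + 0.5)

  shifted <- volume_trace(sim$trace$volume + 100, sim$trace$fs, "s/1")
  sucks2 <- detect_pipeline(shifted, cfg)
  expect_equal(sucks2$onset_s, sucks$onset_s)
  expect_equal(sucks2$size_ml, sucks$size_ml, tolerance = 1e-6)

  meta <- measurement_meta("s", 1)
  expect_true(all(extract_intervals(sucks, meta)$interval_s > 0))
})
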