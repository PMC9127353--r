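# Shared fixtures: hand-built speed/volume signals with known structure.

# raised-cosine speed pulse: amplitude A ml/s, width W s -> area A*W/2 ml
rc_pulse <- function(amplitude, width, fs) {
  t <- seq_len(round(width * fs)) / fs
  amplitude / 2 * (1 - cos(2 * pi * t / width))
}

# place pulses at given onset times on a zero baseline
make_speed <- function(onsets, amplitude, width, fs, total_s) {
  sp <- numeric(round(total_s * fs))
  for (o in onsets) {
    idx <- round(o * fs) + seq_len(round(width * fs))
    sp[idx] <- sp[idx] + rc_pulse(amplitude, width, fs)
  }
  sp
}

as_speed_trace <- function(speed, fs, t0 = 0) {
  structure(list(speed = speed, fs = fs,
                 artifact_mask = rep(FALSE, length(speed)),
                 measurement_id = "fixture", t0 = t0),
            class = "speed_trace")
}

# brute-force crossing of two weighted normal densities: coarse scan for the
# dominance sign change, then a fine grid at the stated resolution
grid_intersection <- function(w1, m1, s1, w2, m2, s2, step = 1e-6) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  coarse <- seq(m1, m2, by = 1e-3)
  fc <- f(coarse)
  sgn <- which(fc[-length(fc)] > 0 & fc[-1] <= 0)
  if (length(sgn) == 0) stop("no crossing found by grid oracle")
  lo <- coarse[sgn[1]]
  fine <- seq(lo - 1e-3, lo + 2e-3, by = step)
  ff <- f(fine)
  k <- which(ff[-length(ff)] > 0 & ff[-1] <= 0)[1]
  (fine[k] + fine[k + 1]) / 2
}

write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
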