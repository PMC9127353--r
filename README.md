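# bpcd — burst-pause criterion derivation for drinkometer recordings

Human ingestive behavior recorded with a drinkometer (a device logging the
cumulative volume of a liquid meal at ~1000 Hz) is organized on two time
scales: individual **sucks**, and **bursts** of sucks separated by longer
pauses. Suck-level parameters (counts, sizes, durations) can be computed
directly; burst-level parameters require a **burst-pause criterion (PC)** —
the pause duration separating within-burst pauses (inter-suck intervals,
ISIs) from between-burst pauses (inter-burst intervals, IBIs). `bpcd`
derives that criterion from the data instead of assuming it:

1. **Detection** — zero-phase low-pass filtering of the volume signal,
   differentiation to consumption speed (ml/s), artifact deletion with
   linear interpolation, amplitude flooring, and peak-based suck detection
   with minimum size and spacing thresholds.
2. **Mixture model** — the pooled pauses are log-transformed and fitted
   with k-component Gaussian mixtures by EM (`fit_gmm`); the component
   count is chosen by AIC = 2p − 2 lnL with p = 3k − 1 (`select_k`).
3. **Criterion** — the PC is the crossing point of the two dominant
   weighted component densities, solved in closed form
   (`component_intersection`) and back-transformed to seconds
   (`derive_pc`): intervals below it are more probably ISIs, at or above it
   more probably IBIs.
4. **Verification** — Kaplan-Meier curves of the ISI sets extracted under
   the derived and arbitrary criteria, an omnibus log-rank test, median
   quotients (100·median/PC) and 0.25 s residual bins (`compare_pcs`,
   `median_quotient`, `bin_residuals`).
5. **Tables** — per-measurement macro- and microstructural parameters at a
   chosen PC (`segment_bursts`, `build_parameter_table`).

A simulator with analytic ground truth (`simulate_trace`,
`simulate_intervals`, `true_intersection`) makes every stage testable
without device data, and a CLI (`bpcd_main`, installed at
`system.file("cli", "bpcd", package = "bpcd")`) exposes the workflow as
subcommands (`simulate`, `qc-plot`, `extract-isis`, `isi-hist`, `fit-gmm`,
`derive-pc`, `km-verify`, `extract-tables`) with YAML configs and
provenance records. Traces are read from a portable CSV dialect
(`time_s,volume_ml`) or from the device's native TDMS files via a channel
map.

## Worked example

```r
library(bpcd)

# simulate one long recording with known ground truth
cfg <- sim_config(seed = 42, n_bursts = 120)
sim <- simulate_trace(cfg)

# detect sucks with settings matched to the simulated device
sucks     <- detect_pipeline(sim$trace, sim_detection_config(cfg))
intervals <- extract_intervals(sucks, measurement_meta("sim", 1))

# mixture fit on log-intervals, component count by AIC
scan <- select_k(log_transform(intervals), k_max = 5, restarts = 10, seed = 42)
pc   <- derive_pc(scan$fits[[as.character(scan$k)]])
cmp  <- compare_pcs(intervals, c(pc$pc_s, 3.15, 5.13, Inf))
```

which prints (abridged):

```
<mixture_scan> AIC by component count:
     1      2      3      4      5
927.77 909.99 915.75 921.82 927.81
chosen k = 2
<pause_criterion> PC = 2.3426 s (log_e 0.8512), components 1 & 2, pairwise_intersection
<km_comparison> group sizes:
PC=2.34257    PC=3.15    PC=5.13        all
       339        369        409        425
log-rank: chi2 = 53.643, df = 2, p = 2.25e-12
```

Reading the numbers: AIC picks two mixture components, as expected when the
pauses really come from an ISI and an IBI regime. The derived criterion,
2.34 s, estimates the generating model's analytic crossing
(`exp(true_intersection(cfg))` = 2.03 s; single-series estimates carry
sampling noise — see the vignette). The KM group sizes grow with the
criterion because the extracted sets are nested, and the log-rank test
rejects the hypothesis that ISI sets extracted under the three criteria
share one time-to-event distribution. The median quotient of the derived-PC
curve is 43% — its median sits near the middle of [0, PC], the signature of
a well-placed criterion, whereas over-long criteria push the quotient far
below 50%. `build_parameter_table()` then yields the per-measurement
summary (426 sucks, 87 bursts, 4.9 sucks/burst, mean ISI 1.08 s, mean IBI
4.09 s at this PC).

## Documentation

The methods vignette (`vignettes/bpcd-methods.Rmd`) documents the model and
its assumptions, every tunable threshold with units and defaults, the
simulator's scope, numerical choices, and known limitations.
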