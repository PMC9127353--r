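test_that("component intersection has the known closed forms", {
  # symmetric equal-weight, equal-sd: midpoint
  expect_equal(component_intersection(0.5, 0, 1, 0.5, 2, 1), 1,
               tolerance = 1e-12)
  # unequal weights, equal sds: linear solution 1 + ln(3)/2
  expect_equal(component_intersection(0.75, 0, 1, 0.25, 2, 1),
               1 + log(3) / 2, tolerance = 1e-9)
  expect_error(component_intersection(0.5, 2, 1, 0.5, 0, 1), "m1 < m2")
  expect_error(component_intersection(0.5, 0, -1, 0.5, 2, 1), "positive")
})

test_that("component intersection agrees with the grid-search oracle", {
  # the spec case: unequal sds
  expect_equal(component_intersection(0.5, 0, 0.5, 0.5, 2, 1),
               grid_intersection(0.5, 0, 0.5, 0.5, 2, 1), tolerance = 1e-5)
  set.seed(99)
  n_checked <- 0
  while (n_checked < 100) {
    m1 <- runif(1, -1, 0); m2 <- m1 + runif(1, 0.8, 2.5)
    s1 <- runif(1, 0.2, 0.7); s2 <- runif(1, 0.2, 0.7)
    w1 <- runif(1, 0.25, 0.75); w2 <- 1 - w1
    ours <- tryCatch(component_intersection(w1, m1, s1, w2, m2, s2),
                     error = function(e) NULL)
    if (is.null(ours)) next # genuinely non-crossing draw
    n_checked <- n_checked + 1
    expect_lt(abs(ours - grid_intersection(w1, m1, s1, w2, m2, s2)), 1e-5)
  }
})

test_that("criterion derivation picks the dominant pair and back-transforms", {
  sym <- structure(list(k = 2L, weights = c(0.5, 0.5), means = c(0, 2),
                        sds = c(1, 1), loglik = 0, aic = 0, n_params = 5L,
                        converged = TRUE, n_restarts_used = 1L, seed = 1L,
                        n = 10L), class = "mixture_fit")
  pc <- derive_pc(sym)
  expect_equal(pc$pc_log, 1, tolerance = 1e-9)
  expect_equal(pc$pc_s, exp(1), tolerance = 1e-9)
  expect_equal(pc$pc_s, exp(pc$pc_log), tolerance = 1e-12)
  expect_true(pc$pc_log > sym$means[1] && pc$pc_log < sym$means[2])
  expect_equal(nrow(pc$candidates), 1L)

  # the local-minimum variant coincides for a clearly bimodal two-component
  # mixture (means 4 sds apart; at 2 sds the mixture is already unimodal and
  # no interior minimum exists)
  bim <- structure(list(k = 2L, weights = c(0.5, 0.5), means = c(0, 4),
                        sds = c(1, 1), loglik = 0, aic = 0, n_params = 5L,
                        converged = TRUE, n_restarts_used = 1L, seed = 1L,
                        n = 10L), class = "mixture_fit")
  pc_min <- derive_pc(bim, method = "mixture_local_minimum")
  expect_equal(pc_min$pc_log, derive_pc(bim)$pc_log, tolerance = 1e-5)
  expect_error(derive_pc(sym, method = "mixture_local_minimum"),
               "no-intersection")

  k1 <- structure(list(k = 1L, weights = 1, means = 0, sds = 1),
                  class = "mixture_fit")
  expect_error(derive_pc(k1), "criterion-undefined")
})

test_that("k = 3 fits report one candidate per density valley", {
  set.seed(12)
  x <- c(rnorm(300, -2, 0.3), rnorm(300, 0, 0.3), rnorm(300, 2, 0.3))
  fit <- fit_gmm(x, 3, restarts = 10, seed = 12)
  pc <- derive_pc(fit)
  expect_equal(nrow(pc$candidates), 2L)
  expect_equal(pc$candidates$pc_s, exp(pc$candidates$pc_log))
  # the headline pc comes from the two heaviest components
  expect_length(pc$component_pair, 2L)
})

test_that("interval classification partitions exactly at the criterion", {
  tab <- interval_table(rep("p", 4), rep(1L, 4), c(0.5, 1.0, 2.0, 5.0))
  parts <- classify_intervals(tab, 1.34)
  expect_equal(parts$isi$interval_s, c(0.5, 1.0))
  expect_equal(parts$ibi$interval_s, c(2.0, 5.0))
  expect_equal(nrow(parts$isi) + nrow(parts$ibi), nrow(tab))

  # boundary value counts as an inter-burst interval
  tab2 <- interval_table("p", 1L, 1.34)
  parts2 <- classify_intervals(tab2, 1.34)
  expect_equal(nrow(parts2$isi), 0L)
  expect_equal(nrow(parts2$ibi), 1L)

  # infinite sentinel: everything is an ISI
  parts3 <- classify_intervals(tab, Inf)
  expect_equal(nrow(parts3$isi), 4L)
  expect_equal(nrow(parts3$ibi), 0L)
})

test_that("the derived criterion is scale-equivariant", {
  sim <- simulate_intervals(sim_config(seed = 14), n = 800)
  fit1 <- fit_gmm(log_transform(sim$table), 2, restarts = 5, seed = 3)
  pc1 <- derive_pc(fit1)
  for (c_scale in c(0.5, 3)) {
    scaled <- sim$table
    scaled$interval_s <- scaled$interval_s * c_scale
    fit2 <- fit_gmm(log_transform(scaled), 2, restarts = 5, seed = 3)
    pc2 <- derive_pc(fit2)
    expect_equal(pc2$pc_log, pc1$pc_log + log(c_scale), tolerance = 1e-6)
    expect_equal(pc2$pc_s, pc1$pc_s * c_scale, tolerance = 1e-6)
  }
})

test_that("criterion recovery: unbiased at study size, consistent at large n", {
  cfg <- sim_config()
  target <- true_intersection(cfg)
  # at the pooled study size the single-sample estimate is noisy (the two
  # components overlap substantially), but the seed-averaged recovery is close
  errs <- vapply(1:20, function(s) {
    sim <- simulate_intervals(sim_config(seed = 600 + s), n = 1671)
    fit <- fit_gmm(log_transform(sim$table), 2, restarts = 5, seed = s)
    derive_pc(fit)$pc_log - target
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.08)

  # with ample data the estimate converges onto the generating intersection
  for (s in 1:2) {
    sim <- simulate_intervals(sim_config(seed = 3000 + s), n = 1e5)
    fit <- fit_gmm(log_transform(sim$table), 2, restarts = 2, seed = s)
    expect_lt(abs(derive_pc(fit)$pc_log - target), 0.05)
  }
})
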