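#' Log-transform an interval table
#'
#' The burst-pause criterion is derived in the natural-log domain, where the
#' inter-suck and inter-burst interval distributions are approximately
#' Gaussian (i.e. the raw intervals are approximately lognormal).
#'
#' @param table an [interval_table()] (all intervals > 0).
#' @param source label recording what the sample pools: `"pooled"`,
#'   `"per-visit"` or `"per-participant"`.
#' @return an object of class `log_interval_sample` with fields `values`
#'   (log_e seconds), `n` and `source`.
#' @export
log_transform <- function(table, source = "pooled") {
  table <- validate_interval_table(table)
  if (nrow(table) < 2L) {
    stop("degenerate-fit error: need at least 2 intervals", call. = FALSE)
  }
  if (any(table$interval_s <= 0)) {
    stop("domain error: nonpositive interval", call. = FALSE)
  }
  structure(list(values = log(table$interval_s), n = nrow(table),
                 source = source),
            class = "log_interval_sample")
}

# Evaluate/restore the RNG state so seeded fits do not disturb the caller's
# random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Fit a univariate Gaussian mixture to log-intervals by EM
#'
#' Maximum-likelihood fit of a k-component univariate Gaussian mixture via
#' expectation-maximization. Each restart initializes the component means at
#' evenly spaced sample quantiles plus seeded jitter, the standard deviations
#' at the sample standard deviation, and the weights uniformly; the best
#' restart by log-likelihood is returned. EM stops when the log-likelihood
#' improves by less than `1e-8` or after 500 iterations. Standard deviations
#' are floored at `1e-3` log-seconds to prevent component collapse on
#' duplicated intervals.
#'
#' @param sample a [log_transform()] result, or a bare numeric vector of
#'   log_e intervals.
#' @param k number of mixture components (>= 1); requires `n >= 3k`.
#' @param restarts number of EM restarts (default 10).
#' @param seed integer seed making the fit reproducible.
#' @return an object of class `mixture_fit` with fields `k`, `weights`,
#'   `means`, `sds` (components sorted by mean), `loglik`, `aic`
#'   (`2(3k-1) - 2 loglik`), `n_params`, `converged`, `n_restarts_used`,
#'   `seed`, `n`, and `loglik_trace` of the winning run.
#' @export
fit_gmm <- function(sample, k, restarts = 10, seed = 1) {
  x <- if (inherits(sample, "log_interval_sample")) sample$values else
    as.numeric(sample)
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > 64L) stop("k too large (max 64)", call. = FALSE)
  n_min <- if (k == 1L) 2L else 3L * k
  if (n < n_min) {
    stop("degenerate-fit error: need n >= ", n_min, " observations (n = ", n,
         ", k = ", k, ")", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate-fit error: all values identical", call. = FALSE)
  }

  sd_floor <- 1e-3
  sx <- stats::sd(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      q <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      mu0 <- q + stats::rnorm(k, 0, sx / 10)
      fit <- .em_run(x, rep(1 / k, k), mu0, rep(sx, k),
                     maxit = 500L, tol = 1e-8, sd_floor = sd_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  ord <- order(best$means)
  p <- 3L * k - 1L
  structure(list(k = k,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 sds = best$sds[ord],
                 loglik = best$loglik,
                 aic = 2 * p - 2 * best$loglik,
                 n_params = p,
                 converged = best$converged,
                 n_restarts_used = as.integer(restarts),
                 seed = as.integer(seed),
                 n = n,
                 loglik_trace = best$loglik_trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, loglik = %.4f, AIC = %.4f%s\n",
              x$k, x$n, x$loglik, x$aic,
              if (x$converged) "" else " (not converged)"))
  comp <- data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                     sd = round(x$sds, 4))
  print(comp)
  invisible(x)
}

#' Mixture density of a fit
#'
#' @param fit a `mixture_fit`.
#' @param x log_e interval values at which to evaluate.
#' @return the mixture probability density at `x`.
#' @export
mixture_density <- function(fit, x) {
  dens <- vapply(seq_len(fit$k), function(j) {
    fit$weights[j] * stats::dnorm(x, fit$means[j], fit$sds[j])
  }, numeric(length(x)))
  rowSums(matrix(dens, nrow = length(x)))
}

#' Select the mixture component count by AIC
#'
#' Fits mixtures for `k = 1..k_max` and selects the component count
#' minimizing the Akaike information criterion (`2p - 2 lnL`, `p = 3k - 1`),
#' breaking ties toward the smaller k. Degenerate component counts (too few
#' observations) are skipped with a warning; at least `k = 1` must succeed.
#'
#' @inheritParams fit_gmm
#' @param k_max largest component count to consider (>= 2).
#' @return an object of class `mixture_scan`: list with `fits` (one
#'   `mixture_fit` per successful k, sorted by k), `k` (chosen count), `aic`
#'   (named vector of AIC values).
#' @export
select_k <- function(sample, k_max = 5, restarts = 10, seed = 1) {
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be >= 2", call. = FALSE)
  fits <- list()
  for (k in seq_len(k_max)) {
    f <- tryCatch(fit_gmm(sample, k, restarts = restarts, seed = seed),
                  error = function(e) {
                    if (k == 1L) stop(e)
                    warning("skipping k = ", k, ": ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[as.character(k)]] <- f
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- as.integer(names(fits))
  chosen <- ks[which.min(aic)] # which.min takes the first (smallest k) on ties
  structure(list(fits = fits, k = chosen, aic = stats::setNames(aic, ks)),
            class = "mixture_scan")
}

#' @export
print.mixture_scan <- function(x, ...) {
  cat("<mixture_scan> AIC by component count:\n")
  print(round(x$aic, 2))
  cat("chosen k =", x$k, "\n")
  invisible(x)
}

#' AIC per measurement
#'
#' Model fit normalized by the number of measurements in the dataset, used to
#' compare mixture fits across study populations of different size (AIC
#' scales with sample size, so the raw values are not comparable).
#'
#' @param aic the model's AIC.
#' @param n_measurements number of measurements (test sessions) in the
#'   dataset.
#' @return the ratio `aic / n_measurements`.
#' @export
aic_per_measurement <- function(aic, n_measurements) {
  if (n_measurements <= 0) stop("n_measurements must be positive", call. = FALSE)
  aic / n_measurements
}
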