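#' Kaplan-Meier curve of an interval set
#'
#' Product-limit estimate of the interval survival function. Extracted
#' interval sets contain no censoring (selection truncates the set, not the
#' observation window), so the estimate equals the empirical survival
#' function `S(t) = #{intervals > t} / n`.
#'
#' @param intervals numeric vector of intervals in seconds (all > 0).
#' @param label group label (conventionally the criterion used, or `"all"`).
#' @return an object of class `km_curve`: list with `group_label`,
#'   `event_times` (sorted unique event times), `survival` (S immediately
#'   after each event time), and `n`.
#' @export
km_estimate <- function(intervals, label = "all") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0) stop("empty-group error", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("data error: intervals must be positive and finite", call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(intervals,
                                         rep(1, length(intervals))) ~ 1)
  structure(list(group_label = as.character(label),
                 event_times = sf$time, survival = sf$surv,
                 n = length(intervals)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %s: n = %d, median = %s s\n", x$group_label, x$n,
              tryCatch(format(km_median(x)), error = function(e) "undefined")))
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @return `S(t)` as a right-continuous step function (1 before the first
#'   event).
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

#' Median of a KM curve
#'
#' Standard convention: the smallest event time at which the survival
#' function reaches 0.5 or below.
#'
#' @param curve a `km_curve`.
#' @return the median time in seconds.
#' @export
km_median <- function(curve) {
  hit <- which(curve$survival <= 0.5)
  if (length(hit) == 0) {
    stop("undefined-median error: survival never reaches 0.5", call. = FALSE)
  }
  curve$event_times[hit[1]]
}

#' Compare interval sets extracted under several criteria
#'
#' For each criterion `pc` the extracted group is `{interval < pc}` (an
#' infinite sentinel keeps every interval, the "no criterion" reference).
#' A KM curve is estimated per group and the finite-criterion groups are
#' compared with a log-rank test. Criteria yielding an empty group are
#' dropped with a warning.
#'
#' @param table an [interval_table()].
#' @param pcs numeric vector of at least two criteria in seconds; may include
#'   `Inf`.
#' @param pairwise also run all pairwise log-rank tests between the
#'   finite-criterion groups, with Bonferroni-adjusted p-values (default
#'   `FALSE`; the omnibus test is the primary analysis).
#' @return an object of class `km_comparison`: list with `curves` (list of
#'   `km_curve`), `sizes` (named group sizes), `logrank` (list with `chi2`,
#'   `df`, `p`; `NULL` when fewer than two finite-criterion groups survive),
#'   and, when requested, `pairwise` (data frame with one row per group
#'   pair).
#' @export
compare_pcs <- function(table, pcs, pairwise = FALSE) {
  table <- validate_interval_table(table)
  if (length(pcs) < 2L) {
    stop("comparison error: need at least 2 criteria", call. = FALSE)
  }
  labels <- ifelse(is.finite(pcs), sprintf("PC=%g", pcs), "all")
  curves <- list()
  keep <- logical(length(pcs))
  for (i in seq_along(pcs)) {
    grp <- table$interval_s[table$interval_s < pcs[i] | !is.finite(pcs[i])]
    if (length(grp) == 0) {
      warning("criterion ", pcs[i], " yields an empty group; dropped",
              call. = FALSE)
      next
    }
    keep[i] <- TRUE
    curves[[labels[i]]] <- km_estimate(grp, labels[i])
  }
  if (sum(keep) < 2L) {
    stop("comparison error: fewer than 2 non-empty groups", call. = FALSE)
  }
  fin <- which(keep & is.finite(pcs))
  logrank <- NULL
  if (length(fin) >= 2L) {
    times <- unlist(lapply(fin, function(i) {
      table$interval_s[table$interval_s < pcs[i]]
    }))
    grp <- factor(rep(labels[fin], vapply(fin, function(i) {
      sum(table$interval_s < pcs[i])
    }, integer(1))), levels = labels[fin])
    sd <- survival::survdiff(survival::Surv(times, rep(1, length(times))) ~ grp)
    df <- length(fin) - 1L
    logrank <- list(chi2 = unname(sd$chisq), df = df,
                    p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  }
  pair_tab <- NULL
  if (isTRUE(pairwise) && length(fin) >= 2L) {
    combos <- utils::combn(fin, 2)
    pair_tab <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      i1 <- combos[1, j]; i2 <- combos[2, j]
      g1 <- table$interval_s[table$interval_s < pcs[i1]]
      g2 <- table$interval_s[table$interval_s < pcs[i2]]
      sd2 <- survival::survdiff(
        survival::Surv(c(g1, g2), rep(1, length(g1) + length(g2))) ~
          rep(c(labels[i1], labels[i2]), c(length(g1), length(g2))))
      data.frame(group1 = labels[i1], group2 = labels[i2],
                 chi2 = unname(sd2$chisq),
                 p = stats::pchisq(sd2$chisq, 1, lower.tail = FALSE))
    }))
    pair_tab$p_bonferroni <- pmin(1, pair_tab$p * nrow(pair_tab))
  }
  structure(list(curves = curves,
                 sizes = vapply(curves, `[[`, integer(1), "n"),
                 pcs = pcs[keep], logrank = logrank, pairwise = pair_tab),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("<km_comparison> group sizes:\n")
  print(x$sizes)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank: chi2 = %.3f, df = %d, p = %.3g\n",
                x$logrank$chi2, x$logrank$df, x$logrank$p))
  }
  invisible(x)
}

#' Median quotient of a KM curve relative to its criterion
#'
#' Summarizes where the 50% interval probability sits inside the criterion:
#' `100 * median / pc`, reported to the nearest integer percent. For a
#' well-chosen criterion the median of the extracted inter-suck intervals
#' falls near the middle of `[0, pc]`; much smaller quotients indicate that
#' the criterion admits intervals far beyond the bulk of the distribution.
#'
#' @param curve a `km_curve`, or a single number taken directly as the median
#'   time in seconds.
#' @param pc_s the criterion in seconds.
#' @return list with `pc_s`, `median_s` and `quotient_pct` (nearest integer).
#' @export
median_quotient <- function(curve, pc_s) {
  median_s <- if (inherits(curve, "km_curve")) km_median(curve) else
    as.numeric(curve)
  list(pc_s = pc_s, median_s = median_s,
       quotient_pct = round(100 * median_s / pc_s))
}

#' Bin interval residuals per group
#'
#' Histograms of each group's intervals on a common grid of fixed-width bins
#' (default 0.25 s) starting at zero; bins are left-closed, right-open.
#' Counts per group sum to the group size.
#'
#' @param curves list of groups: `km_curve` objects and/or bare numeric
#'   interval vectors (an empty vector is a valid, all-zero group). A single
#'   `km_curve` or vector is also accepted.
#' @param bin_width bin width in seconds (> 0, default 0.25).
#' @return a data frame with `bin_lo`, `bin_hi` and one count column per
#'   group label.
#' @export
bin_residuals <- function(curves, bin_width = 0.25) {
  if (inherits(curves, "km_curve") || is.numeric(curves)) curves <- list(curves)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  group_times <- lapply(curves, function(cv) {
    if (inherits(cv, "km_curve")) {
      # reconstruct the event multiset from the uncensored KM drops
      rep(cv$event_times, round(-diff(c(1, cv$survival)) * cv$n))
    } else {
      as.numeric(cv)
    }
  })
  labels <- vapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    if (inherits(cv, "km_curve")) cv$group_label
    else if (!is.null(names(curves)[i]) && nzchar(names(curves)[i]))
      names(curves)[i]
    else paste0("group", i)
  }, character(1))
  maxv <- max(c(0, unlist(group_times)))
  n_bins <- max(1L, ceiling(maxv / bin_width + 1e-9))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  for (i in seq_along(group_times)) {
    times <- group_times[[i]]
    idx <- pmin(floor(times / bin_width) + 1L, n_bins)
    out[[labels[i]]] <- tabulate(idx, nbins = n_bins)
  }
  out
}
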