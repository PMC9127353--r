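#' Intersection of two weighted Gaussian component densities
#'
#' Solves `w1 phi(x; m1, s1) = w2 phi(x; m2, s2)` for the crossing point
#' strictly between the two means. Taking logs turns the equation into a
#' quadratic in x (linear when the standard deviations are equal, with a
#' unique root). When both quadratic roots fall inside `(m1, m2)` the
#' dominance crossing is returned: the root where the left component
#' dominates just below and the right component just above.
#'
#' @param w1,m1,s1 weight, mean and standard deviation of the left (smaller
#'   mean) component.
#' @param w2,m2,s2 weight, mean and standard deviation of the right
#'   component. Requires `m1 < m2`, positive weights and sds.
#' @return the crossing point in the log_e domain.
#' @export
component_intersection <- function(w1, m1, s1, w2, m2, s2) {
  if (!(m1 < m2)) stop("component_intersection: requires m1 < m2", call. = FALSE)
  if (any(c(w1, w2, s1, s2) <= 0)) {
    stop("component_intersection: weights and sds must be positive",
         call. = FALSE)
  }
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  eps <- 1e-12 * (1 / s1^2 + 1 / s2^2)
  if (abs(a) < eps) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      stop("no-intersection error: component densities do not cross",
           call. = FALSE)
    }
    # numerically stable quadratic roots
    q <- -(b + sign(b) * sqrt(disc)) / 2
    roots <- unique(c(q / a, if (q != 0) cc / q else -b / a))
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0) {
    stop("no-intersection error: no crossing strictly between the means ",
         "(components not separated enough)", call. = FALSE)
  }
  if (length(inside) > 1) {
    # keep the dominance crossing (left component higher just below the root)
    f <- function(x) log(w1) - log(s1) - (x - m1)^2 / (2 * s1^2) -
      (log(w2) - log(s2) - (x - m2)^2 / (2 * s2^2))
    ok <- vapply(inside, function(r) {
      d <- min(r - m1, m2 - r) * 1e-3
      f(r - d) > 0 && f(r + d) < 0
    }, logical(1))
    inside <- if (any(ok)) inside[ok][1] else inside[1]
  }
  inside
}

# Local minima of the full mixture density between consecutive component
# means; used as criterion candidates when k > 2.
.mixture_local_minima <- function(fit) {
  ord <- order(fit$means)
  m <- fit$means[ord]
  out <- numeric(0)
  for (i in seq_len(length(m) - 1L)) {
    if (m[i + 1L] - m[i] < 1e-10) next
    opt <- stats::optimize(function(x) mixture_density(fit, x),
                           interval = c(m[i], m[i + 1L]))
    span <- m[i + 1L] - m[i]
    interior <- opt$minimum > m[i] + 1e-6 * span &&
      opt$minimum < m[i + 1L] - 1e-6 * span
    lower <- opt$objective < mixture_density(fit, m[i]) - 1e-12 &&
      opt$objective < mixture_density(fit, m[i + 1L]) - 1e-12
    if (interior && lower) out <- c(out, opt$minimum)
  }
  out
}

#' Derive the burst-pause criterion from a mixture fit
#'
#' The criterion separating inter-suck from inter-burst intervals is the
#' crossing point of the two dominant component densities of the
#' log-interval mixture, back-transformed to seconds. "Dominant" means, by
#' default, the two components with the largest mixing weights
#' (`rank_by = "weight"`); ranking by peak density height
#' (`w / (sd * sqrt(2 pi))`) is available as an alternative. For a
#' two-component mixture the pairwise crossing coincides with the local
#' minimum of the mixture density between the modes; with `k > 2` all local
#' minima of the full mixture density between consecutive component means
#' are additionally reported as candidate criteria.
#'
#' @param fit a `mixture_fit` with `k >= 2`.
#' @param method `"pairwise_intersection"` (default) or
#'   `"mixture_local_minimum"` (place the criterion at the local minimum of
#'   the full mixture density between the two selected component means).
#' @param rank_by how to pick the two dominant components: `"weight"`
#'   (default) or `"peak_density"`.
#' @return an object of class `pause_criterion` with fields `pc_log`, `pc_s`
#'   (`= exp(pc_log)`), `component_pair` (indices into the mean-sorted
#'   components), `candidates` (data frame of all candidate criteria, one row
#'   for `k = 2`), and `method`.
#' @export
derive_pc <- function(fit, method = c("pairwise_intersection",
                                      "mixture_local_minimum"),
                      rank_by = c("weight", "peak_density")) {
  method <- match.arg(method)
  rank_by <- match.arg(rank_by)
  if (!inherits(fit, "mixture_fit")) stop("fit must be a mixture_fit", call. = FALSE)
  if (fit$k < 2L) {
    stop("criterion-undefined error: need at least 2 mixture components",
         call. = FALSE)
  }
  score <- switch(rank_by,
                  weight = fit$weights,
                  peak_density = fit$weights / (fit$sds * sqrt(2 * pi)))
  pair <- sort(order(-score)[1:2])
  i <- pair[1]; j <- pair[2]
  pc_log <- if (method == "pairwise_intersection") {
    component_intersection(fit$weights[i], fit$means[i], fit$sds[i],
                           fit$weights[j], fit$means[j], fit$sds[j])
  } else {
    opt <- stats::optimize(function(x) mixture_density(fit, x),
                           interval = c(fit$means[i], fit$means[j]))
    if (opt$objective >= min(mixture_density(fit, fit$means[i]),
                             mixture_density(fit, fit$means[j]))) {
      stop("no-intersection error: no interior local minimum between the ",
           "selected components", call. = FALSE)
    }
    opt$minimum
  }
  cand_log <- if (fit$k > 2L) .mixture_local_minima(fit) else pc_log
  structure(list(pc_log = pc_log, pc_s = exp(pc_log),
                 component_pair = pair,
                 candidates = data.frame(pc_log = cand_log,
                                         pc_s = exp(cand_log)),
                 method = method),
            class = "pause_criterion")
}

#' @export
print.pause_criterion <- function(x, ...) {
  cat(sprintf("<pause_criterion> PC = %.4f s (log_e %.4f), components %d & %d, %s\n",
              x$pc_s, x$pc_log, x$component_pair[1], x$component_pair[2],
              x$method))
  if (nrow(x$candidates) > 1) {
    cat("candidate criteria (s):",
        paste(sprintf("%.3f", x$candidates$pc_s), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify intervals as ISI or IBI under a criterion
#'
#' Intervals strictly below the criterion are inter-suck intervals (ISIs);
#' intervals at or above it are inter-burst intervals (IBIs). The partition
#' is exact: every row lands in exactly one part. An infinite criterion
#' classifies every interval as an ISI.
#'
#' @param table an [interval_table()].
#' @param pc a `pause_criterion`, or a single positive number in seconds
#'   (`Inf` allowed as the no-criterion sentinel).
#' @return list with elements `isi` and `ibi`, both [interval_table()]s.
#' @export
classify_intervals <- function(table, pc) {
  pc_s <- if (inherits(pc, "pause_criterion")) pc$pc_s else as.numeric(pc)
  if (is.na(pc_s) || pc_s <= 0) stop("pc must be > 0", call. = FALSE)
  table <- validate_interval_table(table)
  is_isi <- table$interval_s < pc_s
  list(isi = validate_interval_table(table[is_isi, , drop = FALSE]),
       ibi = validate_interval_table(table[!is_isi, , drop = FALSE]))
}
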