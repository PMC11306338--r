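# Per-run feature extraction: artifact screening, normalization, crossing
# times (t10/t50), the windowed log-log power-law fit for the exponent b, and
# the time-stretching transform used to compare curve shapes across
# conditions.

#' Screen a trace for bubble artifacts
#'
#' Rejects runs whose O.D. trajectory is unusable: a non-finite tail
#' (incomplete run, typically a bubble entering the light path), non-finite
#' values elsewhere, or an isolated spike. A spike is a step exceeding five
#' times the median absolute inter-sample step that is matched within five
#' samples by a comparable step of opposite sign; monotone growth, however
#' fast, never triggers it.
#'
#' @param trace An [mt_trace()].
#' @return The trace unchanged if accepted; otherwise an object of class
#'   `trace_rejection` with fields `run_id` and `reason` (one of
#'   `"incomplete"`, `"nonfinite"`, `"spike"`).
#' @export
screen_trace <- function(trace) {
  stopifnot(is_mt_trace(trace))
  od <- trace$od
  n <- length(od)
  bad <- !is.finite(od)
  if (any(bad)) {
    first_bad <- which(bad)[1L]
    reason <- if (all(bad[first_bad:n])) "incomplete" else "nonfinite"
    return(trace_rejection(trace$run_id, reason))
  }
  steps <- diff(od)
  med_step <- stats::median(abs(steps))
  thr <- 5 * max(med_step, .Machine$double.eps)
  big <- which(abs(steps) > thr)
  for (i in big) {
    partners <- big[big > i & big <= i + 5L]
    if (any(sign(steps[partners]) == -sign(steps[i]) &
            abs(steps[partners]) > thr)) {
      return(trace_rejection(trace$run_id, "spike"))
    }
  }
  trace
}

trace_rejection <- function(run_id, reason) {
  structure(list(run_id = run_id, reason = reason), class = "trace_rejection")
}

#' @export
print.trace_rejection <- function(x, ...) {
  cat(sprintf("<rejected> %s: %s\n", x$run_id, x$reason))
  invisible(x)
}

#' Test for a screening rejection
#' @param x Object to test.
#' @return `TRUE` if `x` is a `trace_rejection`.
#' @export
is_rejected <- function(x) inherits(x, "trace_rejection")

# Robust plateau estimate: mean of the last 5% of samples, at least 3.
plateau_od <- function(od) {
  n <- length(od)
  k <- max(3L, ceiling(0.05 * n))
  mean(od[(n - k + 1L):n])
}

baseline_od <- function(od) mean(od[seq_len(min(3L, length(od)))])

#' Normalize a trace to \[0, 1\]
#'
#' Maps the O.D. affinely so the curve starts near 0 and plateaus near 1:
#' `od' = (od - od_i) / (od_f - od_i)` with `od_i` the mean of the first three
#' samples and `od_f` the mean of the last 5% of samples (at least three).
#'
#' @param trace An [mt_trace()].
#' @return The normalized trace (attribute `normalized` set). A flat trace
#'   (`od_f` indistinguishable from `od_i`) raises a degenerate-trace error.
#' @export
normalize_trace <- function(trace) {
  stopifnot(is_mt_trace(trace))
  od_i <- baseline_od(trace$od)
  od_f <- plateau_od(trace$od)
  if (!is.finite(od_f - od_i) || (od_f - od_i) < 1e-9) {
    stop_degenerate(sprintf("run %s: flat trace (plateau %.4g ~ baseline %.4g)",
                            trace$run_id, od_f, od_i))
  }
  out <- trace
  out$od <- (trace$od - od_i) / (od_f - od_i)
  attr(out, "normalized") <- TRUE
  out
}

#' Time of first upward crossing of a fraction of the plateau
#'
#' Returns the time at which a normalized trace first crosses `fraction` from
#' below, linearly interpolated between the bracketing samples; `t10` and
#' `t50` are `crossing_time(trace, 0.1)` and `crossing_time(trace, 0.5)`.
#'
#' @param trace A normalized [mt_trace()] (see [normalize_trace()]).
#' @param fraction Threshold in (0, 1).
#' @return Crossing time in seconds; an undefined-crossing error if the
#'   fraction is never reached.
#' @export
crossing_time <- function(trace, fraction) {
  stopifnot(is_mt_trace(trace))
  if (fraction <= 0 || fraction >= 1) stop_input("fraction must be in (0, 1)")
  od <- trace$od
  t <- trace$times
  if (od[1L] >= fraction) return(t[1L])
  above <- od >= fraction
  idx <- which(above & !c(FALSE, above[-length(above)]))  # upward arrivals
  idx <- idx[idx > 1L]
  if (length(idx) == 0L) {
    stop_crossing(sprintf("run %s: fraction %.3g never reached",
                          trace$run_id, fraction))
  }
  i <- idx[1L]
  t[i - 1L] + (fraction - od[i - 1L]) / (od[i] - od[i - 1L]) *
    (t[i] - t[i - 1L])
}

#' Fit the early-phase power law
#'
#' Ordinary least squares of `ln(od)` on `ln(t / t_u)` over samples whose
#' normalized O.D. lies in `[window_lo, window_hi]` (and `t > 0`), the
#' straight-line form of `OD(t) = A (t/t_u)^b`. The slope is the exponent
#' `b`; `A = exp(intercept)`.
#'
#' @param trace A normalized [mt_trace()].
#' @param window_lo,window_hi Normalized O.D. window bounds (defaults 0.1 and
#'   0.4, the approximately linear region of a log-log growth curve).
#' @param t_u Unit time in seconds keeping the law dimensionless; affects only
#'   `A`, never `b`.
#' @return A list with `b`, `A`, `fit_n` (points used) and `fit_r2`. Fewer
#'   than 3 in-window points raise an insufficient-window error.
#' @export
fit_power_law <- function(trace, window_lo = 0.1, window_hi = 0.4, t_u = 1) {
  stopifnot(is_mt_trace(trace))
  if (!(window_lo > 0 && window_lo < window_hi && window_hi < 1)) {
    stop_input("need 0 < window_lo < window_hi < 1")
  }
  keep <- is.finite(trace$od) & trace$od >= window_lo &
    trace$od <= window_hi & trace$times > 0
  if (sum(keep) < 3L) {
    stop_window(sprintf("run %s: only %d samples in O.D. window [%g, %g]",
                        trace$run_id, sum(keep), window_lo, window_hi))
  }
  x <- log(trace$times[keep] / t_u)
  y <- log(trace$od[keep])
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(b = unname(stats::coef(fit)[2L]),
       A = exp(unname(stats::coef(fit)[1L])),
       fit_n = sum(keep),
       fit_r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1)
}

#' Extract the per-run feature set
#'
#' Computes the final O.D. (raw-trace plateau), the crossing times `t10` and
#' `t50` and the power-law exponent `b` (both from the normalized trace), for
#' a trace that has passed [screen_trace()].
#'
#' @param trace An [mt_trace()].
#' @param window_lo,window_hi,t_u Passed to [fit_power_law()].
#' @return A one-row `data.frame` with columns `run_id`, `condition`,
#'   `od_final`, `t10`, `t50`, `b`, `A`, `fit_n`, `fit_r2`, `t_u`, `dT`
#'   (final minus initial temperature, `NA` without a temperature trace).
#' @export
extract_features <- function(trace, window_lo = 0.1, window_hi = 0.4,
                             t_u = 1) {
  stopifnot(is_mt_trace(trace))
  norm <- normalize_trace(trace)
  fit <- fit_power_law(norm, window_lo = window_lo, window_hi = window_hi,
                       t_u = t_u)
  dT <- if (is.null(trace$temperature)) NA_real_ else {
    trace$temperature[length(trace$temperature)] - trace$temperature[1L]
  }
  data.frame(run_id = trace$run_id, condition = trace$condition,
             od_final = plateau_od(trace$od),
             t10 = crossing_time(norm, 0.1),
             t50 = crossing_time(norm, 0.5),
             b = fit$b, A = fit$A, fit_n = fit$fit_n, fit_r2 = fit$fit_r2,
             t_u = t_u, dT = dT,
             stringsAsFactors = FALSE)
}

#' Screen and featurize a whole cohort
#'
#' @param traces List of [mt_trace()] objects.
#' @param ... Passed to [extract_features()].
#' @return A list with `features` (row-bound feature table of accepted runs),
#'   `accepted` (the accepted, un-normalized traces) and `rejections`
#'   (`data.frame` of run ids and reasons, including analysis degeneracies).
#' @export
cohort_features <- function(traces, ...) {
  feats <- list(); kept <- list(); rej <- list()
  for (tr in traces) {
    s <- screen_trace(tr)
    if (is_rejected(s)) {
      rej[[length(rej) + 1L]] <- data.frame(run_id = s$run_id,
                                            reason = s$reason,
                                            stringsAsFactors = FALSE)
      next
    }
    f <- tryCatch(extract_features(s, ...), error = function(e) e)
    if (inherits(f, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(run_id = tr$run_id,
                                            reason = conditionMessage(f),
                                            stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- f
      kept[[length(kept) + 1L]] <- s
    }
  }
  list(features = if (length(feats)) do.call(rbind, feats) else NULL,
       accepted = kept,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(run_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

# Pointwise average of normalized traces on a common time grid.
mean_curve <- function(traces) {
  norm <- lapply(traces, normalize_trace)
  t_max <- min(vapply(norm, function(x) max(x$times), numeric(1)))
  dt <- stats::median(unlist(lapply(norm, function(x) diff(x$times))))
  grid <- seq(0, t_max, by = dt)
  od <- rowMeans(vapply(norm, function(x) {
    stats::approx(x$times, x$od, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
  mt_trace(grid, od, run_id = "mean_curve")
}

#' Time-stretch factor between two cohorts
#'
#' The factor `s = t50(reference mean curve) / t50(group mean curve)`, where
#' each mean curve is the pointwise average of the cohort's normalized traces
#' on a common grid. Multiplying the group's time axis by `s` makes the two
#' mean curves reach their mid-point O.D. simultaneously.
#'
#' @param group,reference Lists of [mt_trace()] objects.
#' @return The scalar stretch factor.
#' @export
stretch_factor <- function(group, reference) {
  if (length(group) == 0L || length(reference) == 0L) {
    stop_input("both cohorts must be non-empty")
  }
  crossing_time(mean_curve(reference), 0.5) /
    crossing_time(mean_curve(group), 0.5)
}

#' Apply time-stretching to a cohort's features
#'
#' Rescales the group's time axis so that its mean-curve `t50` matches the
#' reference's, then rescales every run's time-valued features accordingly.
#' The exponent `b` and the final O.D. are untouched: a pure time rescaling
#' changes neither.
#'
#' @param group_features Feature table of the group (from
#'   [cohort_features()]).
#' @param group,reference Lists of traces behind the group and the reference
#'   (used to form the mean curves), or `NULL` to use `factor` directly.
#' @param factor Optional precomputed stretch factor (overrides the curves).
#' @param mode `"mean_curve"` (default) computes the factor from the averaged
#'   curves; `"per_run"` uses the ratio of the mean per-run `t50` values of
#'   the two feature tables (requires `reference_features`).
#' @param reference_features Feature table of the reference (only for
#'   `mode = "per_run"`).
#' @return A list with `features` (the stretched table) and `factor`.
#' @export
stretch_time <- function(group_features, group = NULL, reference = NULL,
                         factor = NULL, mode = c("mean_curve", "per_run"),
                         reference_features = NULL) {
  mode <- match.arg(mode)
  if (is.null(factor)) {
    factor <- if (mode == "mean_curve") {
      stretch_factor(group, reference)
    } else {
      if (is.null(reference_features)) {
        stop_input("per_run mode needs reference_features")
      }
      mean(reference_features$t50) / mean(group_features$t50)
    }
  }
  out <- group_features
  out$t10 <- out$t10 * factor
  out$t50 <- out$t50 * factor
  list(features = out, factor = factor)
}
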