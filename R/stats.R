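# Cohort statistics: MAD outlier rejection, the assay's standard-error
# convention, cohort summary rows, Mann-Whitney comparisons (measured and
# time-stretched), a four-test normality battery, and Monte-Carlo power.

#' MAD outlier rejection
#'
#' Flags values whose distance from the median exceeds `k` robust standard
#' deviations, the robust deviation being `1.4826 * MAD` with
#' `MAD = median(|x - median(x)|)`. When the MAD is zero (a majority of exact
#' ties) any value differing from the median is rejected.
#'
#' @param values Numeric vector with at least 3 values.
#' @param k Rejection threshold in robust standard deviations (default 3).
#' @return A list with `kept` (values retained), `kept_idx` and
#'   `rejected_idx` (integer indices into `values`).
#' @examples
#' mad_reject(c(1, 2, 3, 4, 100))
#' @export
mad_reject <- function(values, k = 3) {
  if (length(values) < 3L) stop_input("mad_reject needs at least 3 values")
  med <- stats::median(values)
  scale <- stats::mad(values)  # 1.4826 * median absolute deviation
  rejected <- if (scale == 0) values != med else abs(values - med) > k * scale
  list(kept = values[!rejected],
       kept_idx = which(!rejected),
       rejected_idx = which(rejected))
}

#' Standard error, sigma / sqrt(N - 1)
#'
#' The population standard deviation (divisor `N`) divided by `sqrt(N - 1)`;
#' algebraically identical to the sample standard deviation (divisor `N - 1`)
#' divided by `sqrt(N)`.
#'
#' @param values Numeric vector with at least 2 values.
#' @return The standard error.
#' @export
standard_error <- function(values) {
  n <- length(values)
  if (n < 2L) stop_input("standard_error needs at least 2 values")
  stats::sd(values) / sqrt(n)
}

#' Summarize a cohort into a table row
#'
#' Applies [mad_reject()] independently to each of `od_final`, `t10` and `b`;
#' a run flagged on any parameter is dropped from all columns, so a single
#' `N` describes the whole row. Reports mean and standard error
#' (`sigma / sqrt(N - 1)`) per parameter plus the mean temperature change.
#'
#' @param features Feature table from [cohort_features()].
#' @param k MAD threshold passed to [mad_reject()].
#' @return A one-row `data.frame` with columns `condition`, `N`, `dT`, and
#'   `<par>_mean` / `<par>_se` for each parameter; attribute `rejected_runs`
#'   lists run ids removed as outliers.
#' @export
summarize_cohort <- function(features, k = 3) {
  if (is.null(features) || nrow(features) == 0L) {
    stop_input("empty cohort")
  }
  pars <- c("od_final", "t10", "b")
  flagged <- integer(0)
  for (p in pars) {
    flagged <- union(flagged, mad_reject(features[[p]], k = k)$rejected_idx)
  }
  keep <- setdiff(seq_len(nrow(features)), flagged)
  if (length(keep) == 0L) stop_input("all runs rejected as outliers")
  kept <- features[keep, , drop = FALSE]
  row <- data.frame(condition = kept$condition[1L], N = nrow(kept),
                    dT = mean(kept$dT), stringsAsFactors = FALSE)
  for (p in pars) {
    row[[paste0(p, "_mean")]] <- mean(kept[[p]])
    row[[paste0(p, "_se")]] <- if (nrow(kept) > 1L) {
      standard_error(kept[[p]])
    } else 0
  }
  attr(row, "rejected_runs") <- features$run_id[flagged]
  attr(row, "kept_idx") <- keep
  row
}

#' Mann-Whitney U test
#'
#' Rank-based test for a difference in medians. Uses the exact null
#' distribution when both samples are small (`min(n) <= 8`) and untied, and
#' the normal approximation with tie and continuity corrections otherwise
#' (backed by [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative Alternative hypothesis (default two-sided).
#' @return A list with `U` (the statistic for `x` relative to `y`), `p` and
#'   `exact` (whether the exact distribution was used).
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) {
    stop_input("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Compare two cohorts parameter by parameter
#'
#' Mann-Whitney tests on `od_final`, `t10` and `b` as measured, plus `t10`
#' after time-stretching group B onto group A (rescaling B's time axis so the
#' mean-curve `t50` values coincide). Stretching changes neither `b` nor the
#' final O.D., so only `t10` gets a stretched column.
#'
#' @param features_a,features_b Feature tables of the two cohorts (after any
#'   outlier rejection).
#' @param traces_a,traces_b Accepted traces behind the tables, used to build
#'   mean curves; omit them to supply `factor` directly.
#' @param threshold Primary significance threshold (default 1e-3).
#' @param secondary Secondary threshold (default 0.05).
#' @param factor Optional precomputed stretch factor for B onto A.
#' @param stretch_mode Passed to [stretch_time()].
#' @return A `data.frame` with one row per parameter: `parameter`, `U`,
#'   `p_measured`, `p_stretched` (`NA` except for `t10`), and logical
#'   significance flags at both thresholds; attribute `stretch_factor`.
#' @export
compare_groups <- function(features_a, features_b, traces_a = NULL,
                           traces_b = NULL, threshold = 1e-3,
                           secondary = 0.05, factor = NULL,
                           stretch_mode = "mean_curve") {
  pars <- c("od_final", "t10", "b")
  stretched <- stretch_time(features_b, group = traces_b,
                            reference = traces_a, factor = factor,
                            mode = stretch_mode,
                            reference_features = features_a)
  rows <- lapply(pars, function(p) {
    mw <- mann_whitney_u(features_a[[p]], features_b[[p]])
    p_str <- if (p == "t10") {
      mann_whitney_u(features_a$t10, stretched$features$t10)$p
    } else NA_real_
    data.frame(parameter = p, U = mw$U, p_measured = mw$p,
               p_stretched = p_str,
               sig_measured = mw$p < threshold,
               sig_measured_05 = mw$p < secondary,
               sig_stretched = !is.na(p_str) && p_str < threshold,
               sig_stretched_05 = !is.na(p_str) && p_str < secondary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "stretch_factor") <- stretched$factor
  out
}

# Lilliefors statistic: KS distance of the standardized sample against the
# standard normal, with mean and sd estimated from the data.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n))
}

# Cached Monte-Carlo null distributions of the Lilliefors statistic, keyed by
# sample size (draws and seed fixed per key).
.lillie_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, n_draws, seed) {
  key <- paste(n, n_draws, seed, sep = "_")
  if (is.null(.lillie_cache[[key]])) {
    stats0 <- numeric(n_draws)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    for (i in seq_len(n_draws)) {
      stats0[i] <- lilliefors_stat(stats::rnorm(n))
    }
    .lillie_cache[[key]] <- sort(stats0)
  }
  .lillie_cache[[key]]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Lilliefors normality test (Monte-Carlo calibrated)
#'
#' Kolmogorov-Smirnov distance against a normal with estimated mean and
#' standard deviation; the p-value is calibrated against a seeded Monte-Carlo
#' null distribution of the statistic (cached per sample size).
#'
#' @param x Numeric sample.
#' @param n_draws Null draws for the calibration (default 10000).
#' @param seed Seed of the null-draw generator.
#' @return A list with `statistic` and `p`.
#' @export
lilliefors_test <- function(x, n_draws = 10000L, seed = 20260925L) {
  d <- lilliefors_stat(x)
  null <- lilliefors_null(length(x), n_draws, seed)
  list(statistic = d, p = (1 + sum(null >= d)) / (n_draws + 1))
}

#' Jarque-Bera normality test
#'
#' `JB = (N/6) (S^2 + K^2/4)` with `S` the sample skewness and `K` the excess
#' kurtosis (population-moment estimators); p-value from the chi-squared(2)
#' tail.
#'
#' @param x Numeric sample.
#' @return A list with `statistic` and `p`.
#' @export
jarque_bera <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  s <- m3 / m2^1.5
  k <- m4 / m2^2 - 3
  jb <- n / 6 * (s^2 + k^2 / 4)
  list(statistic = jb, p = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Normality battery
#'
#' Runs Anderson-Darling (with the small-sample modification for estimated
#' parameters), one-sample Kolmogorov-Smirnov against a normal with fitted
#' moments, Monte-Carlo-calibrated Lilliefors, and Jarque-Bera. The KS
#' variant with fitted parameters is conservative (its true size is below
#' nominal); Lilliefors is its correctly calibrated counterpart.
#'
#' @param x Numeric sample with at least 8 values.
#' @param alpha Per-test significance level for the `any_fail` flag.
#' @param lilliefors_draws,lilliefors_seed Monte-Carlo settings for
#'   [lilliefors_test()].
#' @return A `data.frame` with columns `test`, `statistic`, `p`; attribute
#'   `any_fail` is `TRUE` if any p-value falls below `alpha`.
#' @export
normality_battery <- function(x, alpha = 0.05, lilliefors_draws = 10000L,
                              lilliefors_seed = 20260925L) {
  if (length(x) < 8L) stop_input("normality_battery needs at least 8 values")
  ad <- nortest::ad.test(x)
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))
  )
  lf <- lilliefors_test(x, n_draws = lilliefors_draws, seed = lilliefors_seed)
  jb <- jarque_bera(x)
  out <- data.frame(
    test = c("anderson_darling", "ks_fitted", "lilliefors", "jarque_bera"),
    statistic = c(unname(ad$statistic), unname(ks$statistic), lf$statistic,
                  jb$statistic),
    p = c(ad$p.value, ks$p.value, lf$p, jb$p),
    stringsAsFactors = FALSE)
  attr(out, "any_fail") <- any(out$p < alpha)
  out
}

#' Statistical power of the Mann-Whitney test by simulation
#'
#' Draws two normal samples per replicate and records how often the
#' Mann-Whitney p-value falls below `alpha`.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and standard deviations
#'   (SDs > 0).
#' @param n_per_group Sample size per group (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param n_sims Number of simulated experiments.
#' @param seed Integer seed.
#' @return The estimated power (fraction of replicates rejecting).
#' @export
power_by_simulation <- function(mean_a, sd_a, mean_b, sd_b, n_per_group,
                                alpha = 0.05, n_sims = 2000L, seed = 1L) {
  if (sd_a <= 0 || sd_b <= 0) stop_input("standard deviations must be > 0")
  if (n_per_group < 2L) stop_input("n_per_group must be >= 2")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_sims)) {
    x <- stats::rnorm(n_per_group, mean_a, sd_a)
    y <- stats::rnorm(n_per_group, mean_b, sd_b)
    if (mann_whitney_u(x, y)$p < alpha) hits <- hits + 1L
  }
  hits / n_sims
}
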