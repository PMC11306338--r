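# End-to-end orchestration: configuration, cohort analysis from manifests,
# and tabular reporting (condition-summary and comparison tables plus a JSON
# log of every rejection).

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default: the log-log fit
#' window (normalized O.D. 0.1-0.4), the unit time, the MAD threshold, the
#' primary (1e-3) and secondary (0.05) significance thresholds, the stretch
#' mode, the normality alpha and the root PRNG seed.
#'
#' @param window_lo,window_hi Fit window bounds, `0 < lo < hi < 1`.
#' @param t_u Unit time in seconds.
#' @param mad_k MAD rejection threshold.
#' @param threshold,secondary Significance thresholds in (0, 1).
#' @param stretch_mode `"mean_curve"` or `"per_run"`.
#' @param normality_alpha Per-test level of the normality battery.
#' @param seed Root seed for any randomness downstream.
#' @return A classed list of validated settings.
#' @export
analysis_config <- function(window_lo = 0.1, window_hi = 0.4, t_u = 1,
                            mad_k = 3, threshold = 1e-3, secondary = 0.05,
                            stretch_mode = "mean_curve",
                            normality_alpha = 0.05, seed = 1L) {
  if (!(window_lo > 0 && window_lo < window_hi && window_hi < 1)) {
    stop_input("need 0 < window_lo < window_hi < 1")
  }
  for (th in c(threshold, secondary, normality_alpha)) {
    if (th <= 0 || th >= 1) stop_input("thresholds must be in (0, 1)")
  }
  structure(list(window_lo = window_lo, window_hi = window_hi, t_u = t_u,
                 mad_k = mad_k, threshold = threshold, secondary = secondary,
                 stretch_mode = stretch_mode,
                 normality_alpha = normality_alpha, seed = as.integer(seed)),
            class = "analysis_config")
}

# Screen, featurize and MAD-summarize one cohort of traces.
analyse_cohort <- function(traces, config) {
  cf <- cohort_features(traces, window_lo = config$window_lo,
                        window_hi = config$window_hi, t_u = config$t_u)
  if (is.null(cf$features)) stop_input("no usable runs in cohort")
  summary <- summarize_cohort(cf$features, k = config$mad_k)
  keep <- attr(summary, "kept_idx")
  list(summary = summary,
       features = cf$features[keep, , drop = FALSE],
       traces = cf$accepted[keep],
       rejections = rbind(
         cf$rejections,
         if (length(attr(summary, "rejected_runs"))) {
           data.frame(run_id = attr(summary, "rejected_runs"),
                      reason = "mad_outlier", stringsAsFactors = FALSE)
         } else NULL))
}

#' Run the full two-cohort analysis
#'
#' Screens both cohorts, extracts features, applies MAD outlier rejection,
#' produces one summary row per condition and the measured/stretched
#' Mann-Whitney comparison table, and logs every rejection. Cohorts may be
#' given as manifests (paths to JSON files), manifest lists, or lists of
#' traces.
#'
#' @param cohort_a,cohort_b Manifest path, manifest list, or list of
#'   [mt_trace()] objects. Cohort A is the reference for time-stretching.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, writes `summary.csv`
#'   (condition rows), `comparisons.csv` and `report.json`.
#' @return A list with `summaries` (two-row `data.frame`), `comparisons`
#'   (from [compare_groups()]), `stretch_factor`, `rejections` and `config`.
#' @export
run_pipeline <- function(cohort_a, cohort_b, config = analysis_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  a <- analyse_cohort(as_traces(cohort_a), config)
  b <- analyse_cohort(as_traces(cohort_b), config)
  comparisons <- compare_groups(a$features, b$features,
                                traces_a = a$traces, traces_b = b$traces,
                                threshold = config$threshold,
                                secondary = config$secondary,
                                stretch_mode = config$stretch_mode)
  report <- list(summaries = rbind(a$summary, b$summary),
                 comparisons = comparisons,
                 stretch_factor = attr(comparisons, "stretch_factor"),
                 rejections = rbind(
                   if (nrow(a$rejections)) cbind(a$rejections, cohort = "A"),
                   if (nrow(b$rejections)) cbind(b$rejections, cohort = "B")),
                 config = unclass(config))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(report$summaries,
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(report$comparisons,
                     file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

# Accept a manifest path, a manifest list, or a list of traces.
as_traces <- function(x, dir = ".") {
  if (is.character(x) && length(x) == 1L) {
    return(read_cohort(read_manifest(x), dir = dirname(x)))
  }
  if (is.list(x) && !is.null(x$files)) {
    return(read_cohort(x, dir = dir))
  }
  if (is.list(x) && all(vapply(x, is_mt_trace, logical(1)))) {
    return(x)
  }
  stop_input("cohort must be a manifest path, manifest list, or list of traces")
}
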