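test_that("screening accepts clean traces and names rejection reasons", {
  clean <- make_avrami_trace()
  expect_identical(screen_trace(clean), clean)

  # NaN tail: incomplete trajectory (bubble entering the light path)
  cut <- clean
  cut$od[400:601] <- NaN
  rej <- screen_trace(cut)
  expect_true(is_rejected(rej))
  expect_equal(rej$reason, "incomplete")

  # interior non-finite value
  hole <- clean
  hole$od[100] <- NA
  expect_equal(screen_trace(hole)$reason, "nonfinite")

  # 3-sample +1.0 spike on a 0 -> 1 sigmoid: both edges exceed 5x the median
  # absolute step (which is well below 0.2 for this fixture), opposite signs
  spiky <- make_avrami_trace(b = 2, tau = 60, od_inf = 1)
  spiky$od[200:202] <- spiky$od[200:202] + 1.0
  expect_equal(screen_trace(spiky)$reason, "spike")

  # fast but monotone growth must not be mistaken for a spike
  fast <- make_avrami_trace(b = 2.5, tau = 10, od_inf = 1.6,
                            times = seq(0, 120, by = 1))
  expect_identical(screen_trace(fast), fast)
})

test_that("normalization is affine-invariant and idempotent", {
  s <- make_avrami_trace(b = 2, tau = 20, od_inf = 1)$od  # shape in [0, 1]
  t <- seq(0, 600, by = 1)
  raw <- mt_trace(t, 0.2 + 1.3 * s)
  norm <- normalize_trace(raw)
  expect_equal(norm$od, normalize_trace(mt_trace(t, s))$od, tolerance = 1e-9)

  # already normalized: unchanged within edge-averaging tolerance
  again <- normalize_trace(norm)
  expect_equal(again$od, norm$od, tolerance = 1e-6)

  # hand value: Avrami b=2, tau=20 gives od'(20) close to 1 - exp(-1)
  fx <- normalize_trace(make_avrami_trace(b = 2, tau = 20, od_inf = 1.5))
  expect_equal(fx$od[fx$times == 20], 0.6321, tolerance = 5e-3)

  expect_error(normalize_trace(mt_trace(0:9, rep(0.3, 10))),
               class = "turbikin_degenerate_trace")
})

test_that("crossing times interpolate the first upward crossing", {
  ramp <- mt_trace(seq(0, 100, by = 1), seq(0, 1, length.out = 101))
  expect_equal(crossing_time(ramp, 0.1), 10)
  expect_equal(crossing_time(ramp, 0.5), 50)

  # Avrami closed-form inversion: t10 = tau * (-ln 0.9)^(1/b)
  av <- normalize_trace(make_avrami_trace(b = 2, tau = 20, od_inf = 1.5))
  expect_equal(crossing_time(av, 0.1), 20 * sqrt(-log(0.9)), tolerance = 0.02)

  expect_error(crossing_time(mt_trace(0:9, rep(0, 10)), 0.5),
               class = "turbikin_undefined_crossing")
  expect_error(crossing_time(ramp, 1.2), class = "turbikin_input_error")
})

test_that("power-law fit is exact on an exact power law", {
  t <- seq(0, 12, by = 0.25)
  tr <- mt_trace(t, 0.001 * t^2.5)
  fit <- fit_power_law(tr)
  expect_equal(fit$b, 2.5, tolerance = 1e-10)
  expect_equal(fit$A, 0.001, tolerance = 1e-10)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)

  # time rescaling leaves the exponent untouched
  for (s in c(0.5, 3, 17)) {
    fit_s <- fit_power_law(mt_trace(t * s, 0.001 * t^2.5))
    expect_equal(fit_s$b, 2.5, tolerance = 1e-9)
  }

  # t_u shifts only the amplitude
  fit_u <- fit_power_law(tr, t_u = 10)
  expect_equal(fit_u$b, fit$b, tolerance = 1e-12)

  expect_error(fit_power_law(mt_trace(0:2, c(0, 0.05, 0.9))),
               class = "turbikin_insufficient_window")
})

test_that("power-law fit agrees with the brute-force OLS oracle", {
  fixtures <- list(
    normalize_trace(make_avrami_trace(b = 2.2, tau = 60, od_inf = 1.4)),
    normalize_trace(make_avrami_trace(b = 3, tau = 35, od_inf = 1.1)),
    {
      set.seed(5)
      raw <- make_avrami_trace(b = 2.5, tau = 50, od_inf = 1.5)
      raw$od <- raw$od + rnorm(length(raw$od), 0, 0.01)
      normalize_trace(raw)
    }
  )
  for (tr in fixtures) {
    fit <- fit_power_law(tr)
    oracle <- brute_force_loglog_fit(tr)
    expect_equal(fit$b, oracle$b, tolerance = 1e-9)
    expect_equal(fit$A, oracle$A, tolerance = 1e-9)
    expect_equal(fit$fit_n, oracle$n)
  }
})

test_that("feature extraction assembles the per-run scalars", {
  ramp <- mt_trace(seq(0, 100, by = 1), seq(0, 1, length.out = 101),
                   run_id = "ramp")
  f <- extract_features(ramp)
  expect_equal(f$t10, 10, tolerance = 0.2)  # edge-averaged normalization
  expect_equal(f$t50, 50, tolerance = 0.2)
  expect_true(f$t10 <= f$t50)

  av <- make_avrami_trace(b = 2, tau = 20, od_inf = 1.5)
  fa <- extract_features(av)
  expect_equal(fa$od_final, 1.5, tolerance = 1e-3)
  expect_true(is.finite(fa$b) && fa$fit_n >= 3)

  expect_error(extract_features(mt_trace(0:9, rep(0.2, 10))),
               class = "turbikin_degenerate_trace")
})

test_that("t10 <= t50 on simulated monotone cohorts", {
  runs <- simulate_cohort(10, kinetic_params(artifact_rate = 0),
                          condition_profiles()$instant, seed = 9)
  feats <- cohort_features(runs)$features
  expect_true(all(feats$t10 <= feats$t50))
})

test_that("time-stretching matches mean-curve t50 and preserves b", {
  runs <- simulate_cohort(8, kinetic_params(artifact_rate = 0),
                          condition_profiles()$instant, seed = 21)
  feats <- cohort_features(runs)$features

  # identity: a group stretched against itself
  self <- stretch_time(feats, group = runs, reference = runs)
  expect_equal(self$factor, 1, tolerance = 1e-12)
  expect_equal(self$features, feats, tolerance = 1e-12)

  # exact inverse: doubling every time axis halves the factor
  doubled <- lapply(runs, function(r) {
    r$times <- r$times * 2
    r
  })
  feats2 <- cohort_features(doubled)$features
  st <- stretch_time(feats2, group = doubled, reference = runs)
  expect_equal(st$factor, 0.5, tolerance = 1e-6)
  expect_equal(st$features$t10, feats$t10, tolerance = 1e-6)
  # the exponent is untouched by stretching, and time-rescaled data refit
  # to the same exponent
  expect_identical(st$features$b, feats2$b)
  expect_equal(feats2$b, feats$b, tolerance = 1e-9)
})
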