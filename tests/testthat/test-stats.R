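test_that("MAD rejection removes gross outliers and respects ties", {
  r <- mad_reject(c(1, 2, 3, 4, 100))
  expect_equal(r.kept <- r$kept, c(1, 2, 3, 4))
  expect_equal(r$rejected_idx, 5L)

  expect_length(mad_reject(rep(7, 6))$rejected_idx, 0L)

  # zero MAD with a deviating minority: only the non-ties go
  r0 <- mad_reject(c(5, 5, 5, 5, 7))
  expect_equal(r0$kept, rep(5, 4))

  expect_error(mad_reject(c(1, 2)), class = "turbikin_input_error")
})

test_that("MAD rejection fraction on normal data matches the tail mass", {
  set.seed(101)
  x <- rnorm(1e5)
  frac <- length(mad_reject(x)$rejected_idx) / length(x)
  # 2 * pnorm(-3) = 0.0027, allow Monte-Carlo + scale-estimation slack
  expect_gt(frac, 0.0018)
  expect_lt(frac, 0.0038)
})

test_that("MAD rejection is near-idempotent: a second pass only shrinks", {
  # removing outliers perturbs the median/MAD slightly, so boundary points
  # can flip on a second pass; that pass can only remove, never resurrect,
  # and on typical contaminated samples it usually changes nothing
  stable <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    x <- c(rnorm(30), rnorm(2, 8))
    once <- mad_reject(x)
    twice <- mad_reject(once$kept)
    expect_true(all(twice$kept %in% once$kept))
    stable[s] <- identical(twice$kept, once$kept)
  }
  expect_gte(mean(stable), 0.75)
})

test_that("standard error follows the sigma/sqrt(N-1) convention", {
  expect_equal(standard_error(c(1, 2, 3)), sqrt(2 / 3) / sqrt(2))
  expect_equal(round(standard_error(c(1, 2, 3)), 4), 0.5774)
  expect_equal(standard_error(rep(4.2, 10)), 0)
  # population-SD/sqrt(N-1) equals sample-SD/sqrt(N)
  set.seed(2)
  x <- rnorm(17)
  sd_pop <- sqrt(mean((x - mean(x))^2))
  expect_equal(standard_error(x), sd_pop / sqrt(length(x) - 1),
               tolerance = 1e-12)
  expect_error(standard_error(3), class = "turbikin_input_error")
})

test_that("cohort summary rejects per run and reports the retained N", {
  feats <- data.frame(
    run_id = sprintf("r%02d", 1:10), condition = "c",
    od_final = rep(1.4, 10), t10 = rep(25, 10), b = rep(2.2, 10),
    dT = rep(0.5, 10), stringsAsFactors = FALSE)
  s <- summarize_cohort(feats)
  expect_equal(s$N, 10)
  expect_equal(s$b_mean, 2.2)
  expect_equal(s$b_se, 0)

  # a 10x b outlier vanishes and takes its whole run with it
  feats$b <- c(rep(2.2, 9), 22) + seq(0, 0.009, length.out = 10)
  feats$od_final <- feats$od_final + seq(0, 0.009, length.out = 10)
  s2 <- summarize_cohort(feats)
  expect_equal(s2$N, 9)
  expect_equal(attr(s2, "rejected_runs"), "r10")
  expect_lt(abs(s2$b_mean - 2.2), 0.01)

  expect_error(summarize_cohort(feats[0, ]), class = "turbikin_input_error")
})

test_that("Mann-Whitney exact p matches hand enumeration", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_true(mw$exact)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)

  # identical samples show no separation
  x <- c(1, 5, 9, 13)
  expect_gte(mann_whitney_u(x, x)$p, 0.99)

  # exact mode equals brute-force enumeration on random untied samples
  set.seed(33)
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    z <- sample(seq(0.01, 1, by = 0.01), n + m)  # untied
    x <- z[seq_len(n)]; y <- z[-seq_len(n)]
    expect_equal(mann_whitney_u(x, y)$p, enumerate_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(4)
  x <- rlnorm(12); y <- rlnorm(15, 0.8)
  p0 <- mann_whitney_u(x, y)$p
  for (f in list(log, sqrt, function(z) z^3, function(z) -1 / z)) {
    expect_equal(mann_whitney_u(f(x), f(y))$p, p0, tolerance = 1e-12)
  }
})

test_that("group comparison flags real separation and not self-comparison", {
  runs <- simulate_cohort(15, kinetic_params(artifact_rate = 0),
                          condition_profiles()$instant, seed = 51)
  feats <- cohort_features(runs)$features
  self <- compare_groups(feats, feats, traces_a = runs, traces_b = runs)
  expect_false(any(self$sig_measured_05))
  expect_true(all(self$p_measured > 0.9))

  # b_true 2.2 vs 3.0 with modest scatter separates decisively
  set.seed(6)
  fa <- feats; fb <- feats
  fa$b <- rnorm(15, 2.2, 0.2); fb$b <- rnorm(15, 3.0, 0.2)
  cmp <- compare_groups(fa, fb, factor = 1)
  expect_true(cmp$sig_measured[cmp$parameter == "b"])
})

test_that("time-scaled copies flag measured t10 but not stretched t10 or b", {
  runs <- simulate_cohort(15, kinetic_params(artifact_rate = 0),
                          condition_profiles()$instant, seed = 77)
  slowed <- lapply(runs, function(r) {
    r$times <- r$times * 2
    r
  })
  feats <- cohort_features(runs)$features
  feats_s <- cohort_features(slowed)$features
  cmp <- compare_groups(feats, feats_s, traces_a = runs, traces_b = slowed)
  expect_true(cmp$sig_measured[cmp$parameter == "t10"])
  expect_false(cmp$sig_stretched[cmp$parameter == "t10"])
  # a pure time rescaling can never flag the exponent
  expect_false(cmp$sig_measured_05[cmp$parameter == "b"])
  expect_equal(attr(cmp, "stretch_factor"), 0.5, tolerance = 1e-6)
})

test_that("Jarque-Bera statistic matches hand-computed moments", {
  # x = {-1, 0, 1}: skewness 0, kurtosis 1.5, JB = (3/6)(0 + (-1.5)^2/4)
  jb <- jarque_bera(c(-1, 0, 1))
  expect_equal(jb$statistic, 0.28125, tolerance = 1e-12)
  expect_equal(jb$p, pchisq(0.28125, 2, lower.tail = FALSE))
})

test_that("Monte-Carlo Lilliefors agrees with the analytic approximation", {
  set.seed(8)
  for (i in 1:3) {
    x <- rnorm(40) + 0.3 * runif(40)
    p_mc <- lilliefors_test(x)$p
    p_ref <- nortest::lillie.test(x)$p.value
    expect_lt(abs(p_mc - p_ref), 0.05)
  }
})

test_that("normality battery detects a uniform sample and validates input", {
  set.seed(9)
  res <- normality_battery(runif(500), lilliefors_draws = 2000L)
  expect_true(attr(res, "any_fail"))
  expect_true(all(res$p[res$test != "ks_fitted"] < 0.01))
  expect_error(normality_battery(rnorm(5)), class = "turbikin_input_error")
})

test_that("normality battery size is near nominal for calibrated tests", {
  n_rep <- 300L
  n <- 80L
  set.seed(12)
  samples <- matrix(rnorm(n_rep * n), nrow = n)
  rej <- matrix(FALSE, n_rep, 4,
                dimnames = list(NULL, c("anderson_darling", "ks_fitted",
                                        "lilliefors", "jarque_bera")))
  for (i in seq_len(n_rep)) {
    res <- normality_battery(samples[, i], lilliefors_draws = 4000L)
    rej[i, res$test] <- res$p < 0.05
  }
  rates <- colMeans(rej)
  # AD and Lilliefors are calibrated at 0.05; binomial 99.9% band for 300 reps
  for (tn in c("anderson_darling", "lilliefors")) {
    expect_gt(rates[[tn]], 0.01)
    expect_lt(rates[[tn]], 0.10)
  }
  # JB converges slowly; allow under-rejection but not over-rejection
  expect_lt(rates[["jarque_bera"]], 0.10)
  # KS with fitted moments is conservative by construction
  expect_lte(rates[["ks_fitted"]], 0.05)
})

test_that("simulated power hits the null level and saturates", {
  p_null <- power_by_simulation(2, 0.3, 2, 0.3, n_per_group = 20,
                                n_sims = 1500, seed = 5)
  expect_gt(p_null, 0.025)
  expect_lt(p_null, 0.08)

  p_sat <- power_by_simulation(0, 1, 10, 1, n_per_group = 10,
                               n_sims = 300, seed = 5)
  expect_gte(p_sat, 0.99)

  expect_error(power_by_simulation(0, 0, 1, 1, 10),
               class = "turbikin_input_error")
})

test_that("simulated power tracks the analytic t-test approximation", {
  # rank-test power ~ t-test power at 0.955 of the sample size (asymptotic
  # relative efficiency under normality); moments as in a 200-repeat design
  sd_pool <- sqrt((0.20^2 + 0.44^2) / 2)
  analytic <- power.t.test(n = round(0.955 * 200), delta = 2.98 - 2.91,
                           sd = sd_pool, sig.level = 0.05)$power
  simulated <- power_by_simulation(2.98, 0.20, 2.91, 0.44, n_per_group = 200,
                                   n_sims = 1500, seed = 3)
  expect_lt(abs(simulated - analytic), 0.06)
})
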