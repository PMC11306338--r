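# Fixtures and independent oracles used across the suite.

# Noiseless Avrami sigmoid trace: od = baseline + od_inf * (1 - exp(-(t/tau)^b))
make_avrami_trace <- function(b = 2, tau = 20, od_inf = 1.5,
                              times = seq(0, 600, by = 1), baseline = 0,
                              run_id = "avrami") {
  mt_trace(times, baseline + od_inf * (1 - exp(-(times / tau)^b)),
           run_id = run_id)
}

# Independent OLS oracle: closed-form cov/var slope and intercept on the
# log-log points inside the window, computed without lm().
brute_force_loglog_fit <- function(trace, window_lo = 0.1, window_hi = 0.4,
                                   t_u = 1) {
  keep <- is.finite(trace$od) & trace$od >= window_lo &
    trace$od <= window_hi & trace$times > 0
  x <- log(trace$times[keep] / t_u)
  y <- log(trace$od[keep])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(b = slope, A = exp(mean(y) - slope * mean(x)), n = length(x))
}

# Brute-force exact Mann-Whitney two-sided p by full enumeration of all
# choose(n + m, n) group assignments of the pooled sample (no ties assumed).
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2, function(ii) {
    xs <- pooled[ii]; ys <- pooled[-ii]
    sum(outer(xs, ys, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Deterministic kinetic parameter sets used in several files.
clean_params <- function(...) {
  kinetic_params(noise_sd = 0, cv_tau = 0, cv_od = 0, artifact_rate = 0, ...)
}

constant_profile <- function(temp = 35) {
  # already equilibrated: start at the target so T(t) is constant
  thermal_profile(T_start = temp, T_ambient = temp, T_local = 0,
                  tau_equil = 1, transfer_delay = 0)
}
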