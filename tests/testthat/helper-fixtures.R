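# fixtures built in code: tiny hand-made time courses and study presets

make_tc <- function(condition_id = "c1", s_g0 = 150, times = c(0, 6, 12, 24),
                    biomass = c(0.5, 1, 2, 4), ethanol = c(0, 5, 15, 40),
                    substrate = NULL, replicate = 1L, ph = 5.5,
                    salinity = "seawater", carbon_source = "glucose") {
  timecourse(condition(condition_id, carbon_source, s_g0, salinity, ph,
                       replicate),
             times, biomass, ethanol, substrate)
}

# a time course whose peak ethanol / biomass / timing are set directly
peak_tc <- function(e_p, x_m, t_peak = 72, s_g0 = 150, s_end = NULL) {
  frac <- c(0, 1 / 3, 2 / 3, 1)
  substrate <- if (is.null(s_end)) NULL else s_g0 + (s_end - s_g0) * frac
  make_tc(s_g0 = s_g0, times = t_peak * frac,
          biomass = x_m * c(0.1, 0.3, 0.6, 1),
          ethanol = e_p * c(0, 0.3, 0.7, 1),
          substrate = substrate)
}

# exponential-limit parameter set: pure Monod growth, no product, no stress
exp_limit_params <- function(s0 = 5000, t_end = 10, dt_out = 1) {
  sim_params(alpha = 0, beta = 0, m_s = 0, ki = NULL, p_crit = NULL,
             s0 = s0, t_end = t_end, dt_out = dt_out)
}

opt_condition <- function(s0 = 150, replicate = 1L) {
  condition("opt", "glucose", s0, "seawater", 4.5, replicate)
}

# replicates with an exact sample mean and standard deviation
mk_group <- function(mean, sd, n = 3) {
  base <- seq_len(n) - (n + 1) / 2          # centered integers
  mean + sd * base / sd(base)
}

# brute-force Monod SSE minimum over an n x n logarithmic parameter grid
grid_search_sse <- function(points, n = 400) {
  rm_grid <- exp(seq(log(0.2 * max(points$rate)), log(10 * max(points$rate)),
                     length.out = n))
  ks_grid <- exp(seq(log(min(points$s[points$s > 0]) / 20),
                     log(20 * max(points$s)), length.out = n))
  best <- Inf
  for (rm in rm_grid) {
    pred <- outer(points$s, ks_grid, function(s, k) rm * s / (k + s))
    sse <- colSums((points$rate - pred)^2)
    best <- min(best, min(sse))
  }
  best
}

# trapezoidal mass-balance residual of an emitted noise-free trajectory:
# (S0 - S) - [dX/y_xs + dP/y_ps + m_s * int X dt], integral taken while S > 0
mass_balance_residual <- function(tc, p) {
  t <- tc$times; X <- tc$biomass; S <- tc$substrate; P <- tc$ethanol
  intX <- cumsum(c(0, diff(t) * (head(X, -1) + tail(X, -1)) / 2 *
                     (head(S, -1) > 0)))
  (S[1] - S) - ((X - X[1]) / p$y_xs + (P - P[1]) / p$y_ps + p$m_s * intX)
}
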