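test_that("yield coefficients divide peak concentrations by initial substrate", {
  tc <- peak_tc(e_p = 89.77, x_m = 7.49, s_g0 = 150)
  y <- yields(tc)
  expect_equal(y$y_ps, 89.77 / 150)     # prints as 0.598
  expect_equal(y$y_xs, 7.49 / 150)      # prints as 0.0499
  expect_identical(round(y$y_ps, 3), 0.598)
  expect_identical(round(y$y_xs, 4), 0.0499)

  zero <- make_tc(ethanol = c(0, 0, 0, 0))
  expect_identical(yields(zero)$y_ps, 0)
})

test_that("volumetric productivity uses the earliest ethanol peak", {
  tc <- peak_tc(e_p = 89.77, x_m = 9.044, t_peak = 72)
  vp <- volumetric_productivity(tc)
  expect_equal(vp$q_p, 89.77 / 72)      # 1.2468 ~ printed 1.247
  expect_identical(vp$t_peak, 72)

  # a tie at the maximum resolves to the earliest time
  flat <- make_tc(times = c(0, 6, 12, 24), ethanol = c(0, 40, 40, 40))
  expect_identical(volumetric_productivity(flat)$t_peak, 6)

  all_zero <- make_tc(ethanol = c(0, 0, 0, 0))
  expect_error(volumetric_productivity(all_zero), "t = 0",
               class = "fermkin_rate_error")
})

test_that("substrate uptake averages consumption over the productivity window", {
  tc <- peak_tc(e_p = 89.77, x_m = 9.044, t_peak = 72, s_g0 = 150, s_end = 6)
  expect_equal(substrate_uptake(tc), (150 - 6) / 72)  # = 2.0

  const <- make_tc(substrate = c(150, 150, 150, 150))
  expect_identical(substrate_uptake(const), 0)

  expect_null(substrate_uptake(make_tc()))
})

test_that("specific production series differentiates ethanol per unit biomass", {
  # linear P, constant X: v = slope / X everywhere (ends included)
  lin <- make_tc(times = c(0, 2, 4, 6, 8), biomass = rep(2, 5),
                 ethanol = 1.0 * c(0, 2, 4, 6, 8))
  expect_equal(specific_production_series(lin)$v, rep(0.5, 5))

  # quadratic P on an even grid: central differences are exact inside
  t <- c(0, 2, 4, 6, 8)
  P <- 2 + 3 * t - 0.1 * t^2
  quad <- make_tc(times = t, biomass = rep(1, 5), ethanol = P)
  v <- specific_production_series(quad)$v
  expect_equal(v[2:4], (3 - 0.2 * t)[2:4])

  # declining P floors at zero
  dec <- make_tc(times = t, biomass = rep(1, 5), ethanol = c(8, 6, 4, 2, 0))
  expect_identical(specific_production_series(dec)$v, rep(0, 5))

  # constant P gives v = 0
  const <- make_tc(ethanol = rep(3, 4))
  expect_identical(specific_production_series(const)$v, rep(0, 4))

  withX0 <- make_tc(times = t, biomass = c(1, 1, 0, 1, 1), ethanol = P)
  expect_error(specific_production_series(withX0), "4",
               class = "fermkin_rate_error")
})

test_that("summary specific rate is the productivity-to-peak-biomass ratio", {
  tc1 <- peak_tc(e_p = 89.77, x_m = 9.044, t_peak = 72)
  s1 <- specific_production_summary(tc1)
  expect_equal(s1$v_g, (89.77 / 72) / 9.044)
  expect_identical(round(s1$v_g, 3), 0.138)

  tc2 <- peak_tc(e_p = 84.48, x_m = 6.944, t_peak = 72)
  expect_identical(round(specific_production_summary(tc2)$v_g, 3), 0.169)
})

test_that("specific growth rate finds the log-linear window", {
  t <- seq(0, 24, by = 4)
  exact <- make_tc(times = t, biomass = 0.5 * exp(0.12 * t),
                   ethanol = seq(0, 60, length.out = length(t)))
  gr <- specific_growth_rate(exact)
  expect_equal(gr$mu, 0.12, tolerance = 1e-10)
  expect_identical(gr$window, c(0, 24))

  # exponential-then-plateau: the window stays inside the exponential phase
  p <- sim_params(s0 = 600, ks = 24.4, ki = NULL, p_crit = 40, n_tox = 2,
                  alpha = 1, beta = 0.05, t_end = 72, dt_out = 1)
  tc <- simulate_batch(p, opt_condition(s0 = 600))
  mu0 <- p$mu_max * 600 / (p$ks + 600)   # generating rate at t -> 0, f = 1
  gr2 <- specific_growth_rate(tc)
  expect_lt(abs(gr2$mu - mu0) / mu0, 0.02)
  expect_lt(gr2$window[2], 36)           # not dragged into the plateau

  dec <- make_tc(biomass = c(4, 3, 2, 1))
  gr3 <- specific_growth_rate(dec)
  expect_identical(gr3$mu, 0)
  expect_null(gr3$window)

  few <- make_tc(biomass = c(0, 0, 1, 2))
  expect_error(specific_growth_rate(few), "4 positive-biomass",
               class = "fermkin_data_error")
})

test_that("descriptor identities hold exactly on every replicate row", {
  p <- sim_params(noise_cv = 0.03)
  recs <- generate_study(p, s0_grid = c(100, 150), ph_grid = c(4.5, 5.5),
                         salinity_grid = "seawater", replicates = 2, seed = 3)
  tab <- descriptor_table(recs)
  reps <- tab[tab$row_type == "replicate", ]
  expect_identical(nrow(reps), 8L)
  expect_equal(reps$y_ps * reps$s_g0, reps$e_p, tolerance = 1e-12)
  expect_equal(reps$y_xs * reps$s_g0, reps$x_m, tolerance = 1e-12)
  expect_equal(reps$v_g * reps$x_m, reps$q_p, tolerance = 1e-12)
  expect_true(all(reps$t_peak %in% recs[[1]]$times))
})

test_that("descriptor table appends per-condition summary rows", {
  p <- sim_params(t_end = 24, dt_out = 4, noise_cv = 0.02)
  recs <- generate_study(p, s0_grid = c(50, 100, 150, 200, 250),
                         ph_grid = 5.5, salinity_grid = "seawater",
                         replicates = 3, seed = 9)
  tab <- descriptor_table(recs)
  expect_identical(sum(tab$row_type == "replicate"), 15L)
  expect_identical(sum(tab$row_type == "summary"), 5L)
  s <- tab[tab$row_type == "summary", ][1, ]
  g <- tab[tab$row_type == "replicate" &
             tab$condition_id == s$condition_id, ]
  expect_equal(s$e_p, mean(g$e_p))
  expect_equal(s$e_p_sd, sd(g$e_p))

  # noise-free replicates have zero dispersion
  p0 <- sim_params(t_end = 24, dt_out = 4, noise_cv = 0)
  recs0 <- generate_study(p0, s0_grid = 150, ph_grid = 5.5,
                          salinity_grid = "seawater", replicates = 3, seed = 9)
  tab0 <- descriptor_table(recs0)
  expect_identical(tab0$e_p_sd[tab0$row_type == "summary"], 0)
})

test_that("the reference preset lands near the expected ethanol yield", {
  p <- sim_params(noise_cv = 0.02)
  recs <- generate_study(p, s0_grid = 150, ph_grid = 5.5,
                         salinity_grid = "seawater", replicates = 3, seed = 5)
  tab <- descriptor_table(recs)
  y_mean <- tab$y_ps[tab$row_type == "summary"]
  expect_lt(abs(y_mean - 0.6) / 0.6, 0.10)
})

test_that("descriptors scale as expected under common rescaling", {
  tc <- peak_tc(e_p = 80, x_m = 8, t_peak = 48)
  c_fac <- 2.5
  tc2 <- tc
  tc2$biomass <- tc$biomass * c_fac
  tc2$ethanol <- tc$ethanol * c_fac
  d1 <- kinetic_descriptors(tc)
  d2 <- kinetic_descriptors(tc2)
  expect_equal(d2$e_p, c_fac * d1$e_p)
  expect_equal(d2$x_m, c_fac * d1$x_m)
  expect_equal(d2$q_p, c_fac * d1$q_p)
  expect_equal(d2$v_g, d1$v_g)
})
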