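#' Generative kinetic parameters for a batch fermentation
#'
#' The simulator couples Monod growth (optionally damped by Andrews substrate
#' inhibition and a product-toxicity term), Luedeking--Piret product
#' formation, and a yield/maintenance substrate balance:
#' \deqn{\mu(S,P) = f \,\mu_{max} \frac{S}{K_s+S}\cdot\frac{1}{1+S/K_i}\cdot
#'       \max(0, 1-P/P_{crit})^{n}}
#' \deqn{dX/dt = \mu X,\quad dP/dt = (\alpha\mu + \beta f)X,\quad
#'       dS/dt = -\frac{1}{Y_{X/S}}\frac{dX}{dt}
#'               -\frac{1}{Y_{P/S}}\frac{dP}{dt} - m_s X}
#' with all rates forced to zero once the substrate is exhausted, and
#' \eqn{f} the environmental stress factor of [stress_factor()].
#'
#' The defaults constitute the package's reference preset for a halotolerant
#' marine yeast fermenting glucose in a seawater-based medium ("ze75-like"):
#' \eqn{\mu_{max}} = 0.141 1/h and \eqn{K_s} = 24.40 g/L, with the remaining
#' constants chosen so that at the base condition (150 g/L glucose, seawater,
#' pH 5.5, 72 h) peak ethanol is near 90 g/L, peak biomass near 9 g/L, and the
#' ethanol optimum over 50--250 g/L initial glucose is interior (near
#' 175 g/L).
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param ks half-saturation (substrate affinity) constant, g/L.
#' @param ki Andrews substrate-inhibition constant, g/L; `NULL` disables
#'   substrate inhibition.
#' @param alpha growth-associated product coefficient, g ethanol / g biomass.
#' @param beta non-growth-associated product coefficient,
#'   g ethanol / (g biomass h).
#' @param y_xs biomass-on-substrate yield, g/g (in (0, 1]).
#' @param y_ps product-on-substrate yield, g/g (in (0, 1]).
#' @param m_s maintenance coefficient, g substrate / (g biomass h).
#' @param p_crit ethanol concentration at which growth ceases, g/L; `NULL`
#'   disables product inhibition.
#' @param n_tox product-inhibition exponent (> 0 when `p_crit` is present).
#' @param x0 inoculum biomass, g/L.
#' @param s0 initial substrate, g/L.
#' @param t_end simulation horizon, h.
#' @param dt_out output sampling interval, h.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (0 = noise-free).
#' @param seed integer random seed for the noise stream.
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(mu_max = 0.141, ks = 24.40, ki = 450,
                       alpha = 3.0, beta = 0.18,
                       y_xs = 0.22, y_ps = 0.88, m_s = 0.005,
                       p_crit = 110, n_tox = 2.2,
                       x0 = 0.5, s0 = 150, t_end = 72, dt_out = 4,
                       noise_cv = 0, seed = 1L) {
  stopifnot(mu_max > 0, ks > 0, y_xs > 0, y_xs <= 1, y_ps > 0, y_ps <= 1,
            x0 > 0, s0 > 0, noise_cv >= 0, alpha >= 0, beta >= 0, m_s >= 0,
            t_end > 0, dt_out > 0)
  if (!is.null(ki)) stopifnot(ki > 0)
  if (!is.null(p_crit)) stopifnot(p_crit > 0, n_tox > 0)
  structure(list(mu_max = mu_max, ks = ks, ki = ki, alpha = alpha, beta = beta,
                 y_xs = y_xs, y_ps = y_ps, m_s = m_s, p_crit = p_crit,
                 n_tox = n_tox, x0 = x0, s0 = s0, t_end = t_end,
                 dt_out = dt_out, noise_cv = noise_cv, seed = as.integer(seed)),
            class = "sim_params")
}

#' Environmental stress parameters (cardinal pH and salinity response)
#'
#' @param ph_min,ph_opt,ph_max cardinal pH values (`ph_min < ph_opt <
#'   ph_max`); growth capacity is zero at and outside the extremes and 1 at
#'   the optimum.
#' @param sal_opt salinity treated as optimal, molar NaCl equivalent
#'   (default 0.6 M, i.e. full-strength seawater).
#' @param sal_decay exponential decline rate of growth capacity per molar
#'   NaCl above the optimum, 1/M.
#' @param sal_decay_low exponential decline rate per molar NaCl *below* the
#'   optimum, 1/M: a marine isolate grows best in seawater and somewhat more
#'   slowly in fresher media.
#' @return an object of class `"stress_params"`.
#' @export
stress_params <- function(ph_min = 2.5, ph_opt = 4.5, ph_max = 8.0,
                          sal_opt = 0.6, sal_decay = 0.5,
                          sal_decay_low = 0.25) {
  stopifnot(ph_min < ph_opt, ph_opt < ph_max, sal_decay >= 0,
            sal_decay_low >= 0, sal_opt >= 0)
  structure(list(ph_min = ph_min, ph_opt = ph_opt, ph_max = ph_max,
                 sal_opt = sal_opt, sal_decay = sal_decay,
                 sal_decay_low = sal_decay_low),
            class = "stress_params")
}

#' Multiplicative environmental stress factor in [0, 1]
#'
#' Product of a cardinal-pH term
#' \deqn{\frac{(pH-pH_{min})(pH-pH_{max})}
#'            {(pH-pH_{min})(pH-pH_{max}) - (pH-pH_{opt})^2}}
#' (zero at and outside the cardinal extremes, clipped to [0, 1]) and a
#' salinity term \eqn{\exp(-d_{hi}\max(0, m-m_{opt}) - d_{lo}\max(0,
#' m_{opt}-m))} on the molar NaCl axis of [salinity_to_molar()]. Equals 1 at
#' `(ph_opt, sal_opt)`.
#'
#' @param ph pH value.
#' @param salinity numeric molar NaCl or a water label.
#' @param stress a [stress_params()] object.
#' @return numeric factor in `[0, 1]`.
#' @export
stress_factor <- function(ph, salinity, stress = stress_params()) {
  if (ph <= stress$ph_min || ph >= stress$ph_max) {
    ph_term <- 0
  } else {
    num <- (ph - stress$ph_min) * (ph - stress$ph_max)
    den <- num - (ph - stress$ph_opt)^2
    ph_term <- min(1, max(0, num / den))
  }
  m <- salinity_to_molar(salinity)
  sal_term <- exp(-stress$sal_decay * max(0, m - stress$sal_opt) -
                    stress$sal_decay_low * max(0, stress$sal_opt - m))
  ph_term * sal_term
}

# alias so simulate_batch can build a default condition even though its
# `condition` argument shadows the constructor
.new_condition <- function(...) condition(...)

#' Simulate one noise-free (or noisy) batch fermentation time course
#'
#' Integrates the model of [sim_params()] with a stiff-safe adaptive solver
#' (relative tolerance 1e-8, absolute tolerance 1e-10). Substrate exhaustion
#' is a terminal root: at S = 0 all rates are frozen and the remaining output
#' times carry the exhaustion state with S clamped at 0. Output is sampled at
#' `0, dt_out, 2*dt_out, ..., t_end` independently of the integrator's
#' internal stepping. Noise is applied afterwards iff `noise_cv > 0`
#' (see [add_noise()], seeded from `params$seed`).
#'
#' @param params a [sim_params()] object. `condition$s_g0` overrides
#'   `params$s0` when a condition is supplied.
#' @param condition optional [condition()]; defaults to the base condition
#'   (glucose, `params$s0` g/L, seawater, pH 5.5, replicate 1).
#' @param stress a [stress_params()] object.
#' @return a [timecourse()] including the substrate series.
#' @export
simulate_batch <- function(params, condition = NULL, stress = stress_params()) {
  cond <- condition %||%
    .new_condition("sim", "glucose", params$s0, "seawater", 5.5, 1L)
  s0 <- cond$s_g0
  f <- stress_factor(cond$ph, cond$salinity, stress)

  p <- params
  rhs <- function(t, y, parms) {
    X <- y[1]; P <- y[2]; S <- y[3]
    if (S <= 0) return(list(c(0, 0, 0)))
    mu <- f * p$mu_max * S / (p$ks + S)
    if (!is.null(p$ki)) mu <- mu / (1 + S / p$ki)
    if (!is.null(p$p_crit)) mu <- mu * max(0, 1 - P / p$p_crit)^p$n_tox
    dX <- mu * X
    dP <- (p$alpha * mu + p$beta * f) * X
    dS <- -(dX / p$y_xs + dP / p$y_ps + p$m_s * X)
    list(c(dX, dP, dS))
  }
  rootfun <- function(t, y, parms) y[3]

  times <- seq(0, p$t_end, by = p$dt_out)
  if (times[length(times)] < p$t_end) times <- c(times, p$t_end)

  out <- tryCatch(
    deSolve::lsoda(c(X = p$x0, P = 0, S = s0), times, rhs, parms = NULL,
                   rtol = 1e-8, atol = 1e-10, rootfunc = rootfun),
    error = function(e) {
      stop_classed("fermkin_numeric_error",
                   "integration failed (mu_max=%g, ks=%g, s0=%g): %s",
                   p$mu_max, p$ks, s0, conditionMessage(e))
    })
  out <- as.data.frame(out)

  # pad past a terminal substrate-exhaustion root with the frozen state
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    pad_times <- times[times > last$time]
    if (length(pad_times)) {
      out <- rbind(out[out$time %in% times, , drop = FALSE],
                   data.frame(time = pad_times, X = last$X, P = last$P, S = 0))
    } else {
      out <- out[out$time %in% times, , drop = FALSE]
    }
  }
  out$S <- pmax(out$S, 0)

  tc <- timecourse(cond, out$time, out$X, out$P, out$S)
  if (p$noise_cv > 0) tc <- add_noise(tc, p$noise_cv, p$seed)
  tc
}

#' Apply multiplicative log-normal measurement noise to a time course
#'
#' Each concentration value is multiplied by an independent draw from a
#' log-normal distribution parameterized to mean 1 and coefficient of
#' variation `noise_cv` (concentrations are positive and heteroscedastic).
#' Identical `(tc, noise_cv, seed)` give identical output; `noise_cv = 0`
#' returns the input unchanged.
#'
#' @param tc a [timecourse()].
#' @param noise_cv coefficient of variation (>= 0).
#' @param seed integer seed for the draws.
#' @return a noisy [timecourse()].
#' @export
add_noise <- function(tc, noise_cv, seed) {
  stopifnot(noise_cv >= 0)
  if (noise_cv == 0) return(tc)
  sdlog <- sqrt(log(1 + noise_cv^2))
  meanlog <- -sdlog^2 / 2
  n <- length(tc$times)
  withr::with_seed(as.integer(seed), {
    tc$biomass <- tc$biomass * stats::rlnorm(n, meanlog, sdlog)
    tc$ethanol <- tc$ethanol * stats::rlnorm(n, meanlog, sdlog)
    if (!is.null(tc$substrate)) {
      tc$substrate <- tc$substrate * stats::rlnorm(n, meanlog, sdlog)
    }
  })
  tc
}

#' Generate a factorial study of synthetic batch fermentations
#'
#' One [timecourse()] per grid cell (`s0_grid` x `ph_grid` x `salinity_grid`)
#' per replicate, with per-replicate seeds derived deterministically from
#' `(seed, cell index, replicate)` via [derive_seed()]. Condition metadata is
#' filled in accordingly; condition ids encode the cell.
#'
#' @param base a [sim_params()] object (its `s0` is overridden per cell; its
#'   `noise_cv` applies to every replicate).
#' @param stress a [stress_params()] object.
#' @param s0_grid initial substrate levels, g/L (non-empty).
#' @param ph_grid pH levels (non-empty).
#' @param salinity_grid salinity values (molar or labels; non-empty).
#' @param replicates number of replicates per cell (>= 1).
#' @param seed integer master seed.
#' @param carbon_source carbon source label stored in the conditions.
#' @return list of `timecourse` objects, cells varying fastest over
#'   `s0_grid`, then `ph_grid`, then `salinity_grid`, then replicate.
#' @export
generate_study <- function(base, stress = stress_params(),
                           s0_grid, ph_grid, salinity_grid,
                           replicates = 3L, seed = 1L,
                           carbon_source = "glucose") {
  stopifnot(length(s0_grid) >= 1, length(ph_grid) >= 1,
            length(salinity_grid) >= 1, replicates >= 1)
  cells <- expand.grid(s0 = s0_grid, ph = ph_grid,
                       salinity = as.character(salinity_grid),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells) * replicates)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    id <- sprintf("s%g_ph%g_sal%s", cell$s0, cell$ph, cell$salinity)
    p <- base
    p$s0 <- cell$s0
    for (r in seq_len(replicates)) {
      p$seed <- derive_seed(seed, ci, r)
      cond <- condition(id, carbon_source, cell$s0, cell$salinity, cell$ph,
                        r)
      k <- k + 1L
      out[[k]] <- simulate_batch(p, cond, stress)
    }
  }
  out
}
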