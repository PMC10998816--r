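# Per-condition kinetic summary quantities of a batch fermentation:
# peak ethanol E_p and biomass X_m, coefficient yields Y_P/S and Y_X/S
# referred to the *initial* substrate concentration, volumetric productivity
# Q_p, average substrate uptake Q_s, specific production rate v and specific
# growth rate mu.

#' Ethanol and biomass coefficient yields
#'
#' Yields referred to the initial substrate concentration:
#' `y_ps = max(P) / s_g0`, `y_xs = max(X) / s_g0` (g/g).
#'
#' @param tc a valid [timecourse()] with `condition$s_g0 > 0`.
#' @return list with `y_ps` and `y_xs`.
#' @export
yields <- function(tc) {
  assert_valid_timecourse(tc)
  s_g0 <- tc$condition$s_g0
  list(y_ps = max(tc$ethanol) / s_g0, y_xs = max(tc$biomass) / s_g0)
}

#' Volumetric ethanol productivity
#'
#' Peak ethanol concentration divided by the earliest time attaining it:
#' `q_p = max(P) / t_peak`, g/(L h). The peak must occur at t > 0.
#'
#' @param tc a valid [timecourse()].
#' @return list with `q_p` and `t_peak` (h).
#' @export
volumetric_productivity <- function(tc) {
  assert_valid_timecourse(tc)
  i <- which.max(tc$ethanol)         # earliest index attaining the maximum
  t_peak <- tc$times[i]
  if (t_peak == 0) {
    stop_classed("fermkin_rate_error",
                 "maximum ethanol attained only at t = 0 for '%s': productivity undefined",
                 tc$condition$condition_id)
  }
  list(q_p = tc$ethanol[i] / t_peak, t_peak = t_peak)
}

#' Average substrate uptake rate
#'
#' Substrate consumed per liter per hour over the window `[0, t_peak]` used
#' by [volumetric_productivity()]: `q_s = (S(0) - S(t_peak)) / t_peak`.
#' Returns `NULL` when the time course carries no substrate series.
#'
#' @param tc a valid [timecourse()].
#' @return numeric `q_s` in g/(L h), or `NULL` when substrate is absent.
#' @export
substrate_uptake <- function(tc) {
  assert_valid_timecourse(tc)
  if (is.null(tc$substrate)) return(NULL)
  vp <- volumetric_productivity(tc)
  i <- match(vp$t_peak, tc$times)
  (tc$substrate[1] - tc$substrate[i]) / vp$t_peak
}

#' Time-resolved specific ethanol production rate
#'
#' `v(t) = (dP/dt) / X(t)` in g/(g h), with dP/dt by central differences at
#' interior points and one-sided differences at the ends; negative values are
#' floored at 0. Interior biomass must be positive.
#'
#' @param tc a valid [timecourse()].
#' @return data.frame with columns `time` and `v`.
#' @export
specific_production_series <- function(tc) {
  assert_valid_timecourse(tc)
  t <- tc$times; P <- tc$ethanol; X <- tc$biomass
  n <- length(t)
  interior <- 2:(n - 1)
  if (any(X[interior] == 0)) {
    bad <- interior[which(X[interior] == 0)[1]]
    stop_classed("fermkin_rate_error",
                 "biomass is zero at interior time %g h: specific rate undefined",
                 t[bad])
  }
  dP <- numeric(n)
  dP[1] <- (P[2] - P[1]) / (t[2] - t[1])
  dP[n] <- (P[n] - P[n - 1]) / (t[n] - t[n - 1])
  dP[interior] <- (P[interior + 1] - P[interior - 1]) /
    (t[interior + 1] - t[interior - 1])
  v <- pmax(0, dP / X)
  data.frame(time = t, v = v)
}

#' Summary specific ethanol production rate
#'
#' The table summary `v_g = q_p / x_m` (volumetric productivity divided by
#' peak biomass) — the ratio form that standard descriptor tables report —
#' together with `v_peak`, the pointwise maximum of
#' [specific_production_series()].
#'
#' @param tc a valid [timecourse()].
#' @return list with `v_g` and `v_peak`, g/(g h).
#' @export
specific_production_summary <- function(tc) {
  vp <- volumetric_productivity(tc)
  x_m <- max(tc$biomass)
  if (x_m == 0) {
    stop_classed("fermkin_rate_error",
                 "peak biomass is zero for '%s': specific rate undefined",
                 tc$condition$condition_id)
  }
  list(v_g = vp$q_p / x_m, v_peak = max(specific_production_series(tc)$v))
}

#' Specific growth rate from the logarithmic biomass plot
#'
#' Least-squares slope of `ln X` versus `t` over the contiguous window of at
#' least 4 positive-biomass points that maximizes the regression coefficient
#' of determination, subject to a positive slope (ties broken towards longer,
#' earlier windows). If no positive-slope window exists, `mu = 0` with an
#' empty window.
#'
#' @param tc a valid [timecourse()] with >= 4 positive-biomass points.
#' @return list with `mu` (1/h), `window` (numeric length-2 time interval, or
#'   `NULL`), and `r2` of the selected regression (`NA` when no window).
#' @export
specific_growth_rate <- function(tc) {
  assert_valid_timecourse(tc)
  t <- tc$times; X <- tc$biomass
  if (sum(X > 0) < 4) {
    stop_classed("fermkin_data_error",
                 "fewer than 4 positive-biomass points for '%s': cannot estimate mu",
                 tc$condition$condition_id)
  }
  n <- length(t)
  best <- list(mu = 0, window = NULL, r2 = NA_real_, len = 0L, start = n + 1L)
  tol <- 1e-9
  for (s in 1:(n - 3)) {
    for (e in (s + 3):n) {
      if (any(X[s:e] <= 0)) next
      ti <- t[s:e]; yi <- log(X[s:e])
      vt <- stats::var(ti); vy <- stats::var(yi)
      if (vy == 0) next                       # flat: slope 0, not positive
      slope <- stats::cov(ti, yi) / vt
      if (slope <= 0) next
      r2 <- stats::cor(ti, yi)^2
      len <- e - s + 1L
      better <- (is.na(best$r2) && best$len == 0L) ||
        r2 > best$r2 + tol ||
        (abs(r2 - best$r2) <= tol &&
           (len > best$len || (len == best$len && s < best$start)))
      if (better) {
        best <- list(mu = slope, window = c(t[s], t[e]), r2 = r2,
                     len = len, start = s)
      }
    }
  }
  list(mu = best$mu, window = best$window, r2 = best$r2)
}

#' Assemble a descriptor table from a collection of time courses
#'
#' One row per record (`row_type = "replicate"`) followed by one summary row
#' per condition (`row_type = "summary"`) holding replicate means in the
#' descriptor columns and standard deviations in the matching `*_sd` columns.
#'
#' @param records non-empty list of valid [timecourse()] objects.
#' @return data.frame keyed by `condition_id` and `replicate`.
#' @export
descriptor_table <- function(records) {
  if (!length(records)) {
    stop_classed("fermkin_data_error", "descriptor_table needs at least one record")
  }
  rows <- lapply(records, function(tc) {
    cd <- tc$condition
    d <- tryCatch(kinetic_descriptors(tc), error = function(e) {
      stop_classed(class(e)[1],
                   "condition '%s' (replicate %d): %s",
                   cd$condition_id, cd$replicate, conditionMessage(e))
    })
    data.frame(condition_id = cd$condition_id, carbon_source = cd$carbon_source,
               s_g0 = cd$s_g0, salinity = cd$salinity, ph = cd$ph,
               replicate = cd$replicate, row_type = "replicate",
               e_p = d$e_p, t_peak = d$t_peak, x_m = d$x_m,
               y_ps = d$y_ps, y_xs = d$y_xs, q_p = d$q_p,
               q_s = d$q_s %||% NA_real_, v_g = d$v_g, v_peak = d$v_peak,
               mu = d$mu,
               mu_t0 = if (is.null(d$mu_window)) NA_real_ else d$mu_window[1],
               mu_t1 = if (is.null(d$mu_window)) NA_real_ else d$mu_window[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  metrics <- c("e_p", "t_peak", "x_m", "y_ps", "y_xs", "q_p", "q_s", "v_g",
               "v_peak", "mu")
  for (m in metrics) tab[[paste0(m, "_sd")]] <- NA_real_

  summaries <- lapply(split(tab, factor(tab$condition_id,
                                        levels = unique(tab$condition_id))),
                      function(g) {
    s <- g[1, , drop = FALSE]
    s$replicate <- NA_integer_
    s$row_type <- "summary"
    s$mu_t0 <- NA_real_; s$mu_t1 <- NA_real_
    for (m in metrics) {
      s[[m]] <- mean(g[[m]])
      s[[paste0(m, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[m]]) else NA_real_
    }
    s
  })
  out <- rbind(tab, do.call(rbind, summaries))
  rownames(out) <- NULL
  out
}

#' All kinetic descriptors of one time course
#'
#' Convenience wrapper computing every descriptor at once.
#'
#' @param tc a valid [timecourse()].
#' @return list with `e_p`, `t_peak`, `x_m`, `y_ps`, `y_xs`, `q_p`, `q_s`
#'   (`NULL` when substrate is absent), `v_g`, `v_peak`, `mu`, `mu_window`.
#' @export
kinetic_descriptors <- function(tc) {
  y <- yields(tc)
  vp <- volumetric_productivity(tc)
  sp <- specific_production_summary(tc)
  gr <- specific_growth_rate(tc)
  list(e_p = max(tc$ethanol), t_peak = vp$t_peak, x_m = max(tc$biomass),
       y_ps = y$y_ps, y_xs = y$y_xs, q_p = vp$q_p,
       q_s = substrate_uptake(tc), v_g = sp$v_g, v_peak = sp$v_peak,
       mu = gr$mu, mu_window = gr$window)
}
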