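# Monod saturation model relating a specific rate (growth mu or ethanol
# production v) to initial substrate concentration:
#   rate(S) = rate_max * S / (Ks + S)

#' Monod rate law
#'
#' @param s substrate concentration(s), g/L (>= 0).
#' @param rate_max maximum specific rate (> 0).
#' @param ks half-saturation constant, g/L (> 0).
#' @return rate(s) = `rate_max * s / (ks + s)`.
#' @export
monod <- function(s, rate_max, ks) {
  stopifnot(all(s >= 0), rate_max > 0, ks > 0)
  rate_max * s / (ks + s)
}

#' Hanes--Woolf starting values for a Monod fit
#'
#' Regresses `s/rate` on `s` over points with positive `s` and `rate`; slope
#' `m` and intercept `b` give `rate_max0 = 1/m`, `ks0 = b/m`. Exact on
#' noise-free Monod data. When either value comes out non-positive (e.g.
#' saturated, rate-flat data) the fallback `rate_max0 = 1.2 * max(rate)`,
#' `ks0 = median(s)` is returned.
#'
#' @param points data.frame with columns `s` and `rate`.
#' @return list with `rate_max0` and `ks0`.
#' @export
initial_guess <- function(points) {
  usable <- points$s > 0 & points$rate > 0
  if (sum(usable) < 2) {
    stop_classed("fermkin_data_error",
                 "initial_guess needs at least 2 points with s > 0 and rate > 0 (got %d)",
                 sum(usable))
  }
  s <- points$s[usable]
  y <- s / points$rate[usable]
  vs <- stats::var(s)
  fallback <- list(rate_max0 = 1.2 * max(points$rate), ks0 = stats::median(points$s))
  if (vs == 0) return(fallback)
  m <- stats::cov(s, y) / vs
  b <- mean(y) - m * mean(s)
  if (!is.finite(m) || m <= 0) return(fallback)
  rate_max0 <- 1 / m
  ks0 <- b / m
  if (!is.finite(ks0) || ks0 <= 0 || rate_max0 <= 0) return(fallback)
  list(rate_max0 = rate_max0, ks0 = ks0)
}

#' Fit the Monod model by nonlinear least squares
#'
#' Minimizes `sum((rate_i - monod(s_i, rate_max, ks))^2)` with positivity
#' enforced by optimizing log-parameters (Levenberg--Marquardt; relative
#' SSE tolerance and parameter-step tolerance 1e-10, at most 500 iterations).
#' Starting values come from [initial_guess()] when not supplied. A fit that
#' fails to converge is returned with `converged = FALSE` and diagnostics,
#' never raised. R-squared is `1 - SSE/SST` about the mean rate (the usual
#' nonlinear-regression convention; can be negative for bad fits, and is `NA`
#' with `r2_defined = FALSE` when the rates are constant).
#'
#' @param points data.frame with columns `s` (>= 0) and `rate` (>= 0); at
#'   least 3 points.
#' @param init optional list/vector with starting values `rate_max0`, `ks0`.
#' @param exclude_inhibited if `TRUE`, drop points with `s` above the
#'   rate-maximizing substrate level before fitting (use when the data show a
#'   substrate-inhibition decline the saturation model cannot represent).
#'   Default `FALSE` fits all points.
#' @return an object of class `"monod_fit"`.
#' @export
fit_monod <- function(points, init = NULL, exclude_inhibited = FALSE) {
  stopifnot(is.data.frame(points), all(c("s", "rate") %in% names(points)))
  points <- points[is.finite(points$s) & is.finite(points$rate), , drop = FALSE]
  if (nrow(points) < 3) {
    stop_classed("fermkin_data_error",
                 "fit_monod needs at least 3 points (got %d)", nrow(points))
  }
  if (any(points$s < 0) || any(points$rate < 0)) {
    stop_classed("fermkin_validation_error",
                 "fit_monod requires non-negative s and rate")
  }
  if (exclude_inhibited) {
    s_star <- points$s[which.max(points$rate)]
    points <- points[points$s <= s_star, , drop = FALSE]
    if (nrow(points) < 3) {
      stop_classed("fermkin_data_error",
                   "fewer than 3 points remain after excluding the inhibited branch")
    }
  }
  s <- points$s; rate <- points$rate
  if (is.null(init)) {
    init <- tryCatch(initial_guess(points), error = function(e) {
      list(rate_max0 = 1.2 * max(rate, 1e-6), ks0 = max(stats::median(s), 1e-6))
    })
  } else if (!is.list(init)) {
    init <- list(rate_max0 = init[[1]], ks0 = init[[2]])
  }
  stopifnot(init$rate_max0 > 0, init$ks0 > 0)

  resid_fn <- function(lp) rate - exp(lp[1]) * s / (exp(lp[2]) + s)
  fit <- minpack.lm::nls.lm(
    par = log(c(init$rate_max0, init$ks0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                         ptol = 1e-10))
  rate_max <- exp(fit$par[1]); ks <- exp(fit$par[2])
  sse <- sum(resid_fn(fit$par)^2)
  sst <- sum((rate - mean(rate))^2)
  n <- length(s)

  se <- c(NA_real_, NA_real_)
  if (n > 2 && !is.null(fit$hessian)) {
    cv <- tryCatch(solve(fit$hessian) * sse / (n - 2), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) {
      se_log <- sqrt(diag(cv))
      se <- c(rate_max * se_log[1], ks * se_log[2])  # delta method
    }
  }
  structure(list(rate_max = rate_max, ks = ks,
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 r2_defined = sst > 0,
                 sse = sse, sst = sst, n = n,
                 converged = fit$info %in% 1:4,
                 info = fit$info, message = fit$message,
                 niter = fit$niter,
                 se_rate_max = se[1], se_ks = se[2],
                 init_rate_max = init$rate_max0, init_ks = init$ks0),
            class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("<monod_fit> rate_max = %.6g (se %.3g), Ks = %.6g (se %.3g) g/L\n",
              x$rate_max, x$se_rate_max, x$ks, x$se_ks))
  cat(sprintf("  n = %d, SSE = %.4g, R2 = %s, converged = %s (%d iterations)\n",
              x$n, x$sse,
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined",
              x$converged, x$niter))
  invisible(x)
}

#' Replicate-averaged specific rates versus initial substrate concentration
#'
#' For each condition in `records`, the specific growth rate `mu` or the
#' summary specific production rate `v_g` is computed per replicate and
#' averaged, then paired with the condition's initial substrate level — the
#' point set the Monod model is fitted to.
#'
#' @param records list of valid [timecourse()] objects spanning at least 3
#'   distinct `s_g0` levels.
#' @param which `"growth"` (mu) or `"production"` (v_g).
#' @return data.frame with columns `s` and `rate`, sorted by `s`.
#' @export
rate_vs_substrate <- function(records, which = c("growth", "production")) {
  which <- match.arg(which)
  tab <- descriptor_table(records)
  reps <- tab[tab$row_type == "replicate", ]
  if (length(unique(reps$s_g0)) < 3) {
    stop_classed("fermkin_data_error",
                 "rate_vs_substrate needs records spanning >= 3 distinct s_g0 levels")
  }
  metric <- if (which == "growth") "mu" else "v_g"
  agg <- stats::aggregate(reps[[metric]],
                          by = list(condition_id = reps$condition_id,
                                    s = reps$s_g0),
                          FUN = mean)
  out <- data.frame(s = agg$s, rate = agg$x)
  out[order(out$s), , drop = FALSE]
}

#' Monte-Carlo parameter-recovery harness for the Monod fit
#'
#' For each replicate, rates are generated as `monod(s, true_rate_max,
#' true_ks)` times multiplicative log-normal noise with mean 1 and
#' coefficient of variation `noise_cv` (per-replicate seeds derived from
#' `seed`), then refitted with [fit_monod()].
#'
#' @param true_rate_max,true_ks generating parameters.
#' @param s_grid substrate levels, g/L.
#' @param noise_cv coefficient of variation of the rate noise (>= 0).
#' @param n_rep number of Monte-Carlo replicates (>= 1).
#' @param seed integer master seed.
#' @return list with `fits` (data.frame: replicate, rate_max, ks, r2,
#'   converged) and `summary` (per-parameter median estimate, relative median
#'   bias, and RMSE).
#' @export
recovery_experiment <- function(true_rate_max, true_ks, s_grid, noise_cv,
                                n_rep, seed = 1L) {
  stopifnot(n_rep >= 1, noise_cv >= 0)
  truth <- monod(s_grid, true_rate_max, true_ks)
  sdlog <- sqrt(log(1 + noise_cv^2)); meanlog <- -sdlog^2 / 2
  rows <- lapply(seq_len(n_rep), function(r) {
    rates <- truth
    if (noise_cv > 0) {
      withr::with_seed(derive_seed(seed, r), {
        rates <- truth * stats::rlnorm(length(truth), meanlog, sdlog)
      })
    }
    fit <- fit_monod(data.frame(s = s_grid, rate = rates))
    data.frame(replicate = r, rate_max = fit$rate_max, ks = fit$ks,
               r2 = fit$r2, converged = fit$converged)
  })
  fits <- do.call(rbind, rows)
  summ <- data.frame(
    parameter = c("rate_max", "ks"),
    true = c(true_rate_max, true_ks),
    median_estimate = c(stats::median(fits$rate_max), stats::median(fits$ks)),
    rmse = c(sqrt(mean((fits$rate_max - true_rate_max)^2)),
             sqrt(mean((fits$ks - true_ks)^2))))
  summ$median_bias_rel <- (summ$median_estimate - summ$true) / summ$true
  list(fits = fits, summary = summ)
}
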