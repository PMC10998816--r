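#' Condition metadata for one fermentation
#'
#' Describes the environment of a single batch culture: carbon source, the
#' initial substrate concentration the yield coefficients are referred to,
#' salinity (either a molar NaCl concentration or one of the water labels
#' `"seawater"`, `"half_seawater"`, `"distilled"`), initial pH, and the
#' replicate index.
#'
#' @param condition_id character label identifying the condition (shared by
#'   its replicates).
#' @param carbon_source character, e.g. `"glucose"`.
#' @param s_g0 initial substrate concentration, g/L (must be > 0).
#' @param salinity numeric molar NaCl, or one of `"seawater"`,
#'   `"half_seawater"`, `"distilled"`. Stored as character.
#' @param ph initial pH (0--14).
#' @param replicate positive integer replicate index.
#' @return an object of class `"condition"` (a named list).
#' @export
condition <- function(condition_id, carbon_source = "glucose", s_g0,
                      salinity = "seawater", ph = 5.5, replicate = 1L) {
  structure(list(condition_id = as.character(condition_id),
                 carbon_source = as.character(carbon_source),
                 s_g0 = as.numeric(s_g0),
                 salinity = as.character(salinity),
                 ph = as.numeric(ph),
                 replicate = as.integer(replicate)),
            class = "condition")
}

#' Molar NaCl equivalent of a salinity value
#'
#' Water labels map to molar equivalents on a single numeric axis:
#' `distilled` = 0 M, `half_seawater` = 0.3 M, `seawater` = 0.6 M
#' (seawater carries roughly 35 g/L salt). Numeric strings pass through.
#'
#' @param salinity character or numeric salinity.
#' @return molar NaCl concentration (numeric scalar).
#' @export
salinity_to_molar <- function(salinity) {
  if (is.numeric(salinity)) return(as.numeric(salinity))
  s <- as.character(salinity)
  labels <- c(distilled = 0, half_seawater = 0.3, seawater = 0.6)
  if (s %in% names(labels)) return(unname(labels[s]))
  m <- suppressWarnings(as.numeric(s))
  if (is.na(m)) {
    stop_classed("fermkin_validation_error",
                 "unrecognized salinity value '%s' (expected molar NaCl or one of %s)",
                 s, paste(names(labels), collapse = ", "))
  }
  m
}

#' A single batch-fermentation time course
#'
#' One condition's sampled trajectory: biomass X(t), ethanol P(t) and
#' (optionally) substrate S(t), all in g/L, over time in hours. Substrate may
#' be absent; descriptors that need it are then reported as absent.
#'
#' @param condition a [condition()] object.
#' @param times strictly increasing sampling times starting at 0, h (>= 3
#'   points).
#' @param biomass biomass (dry weight) series, g/L.
#' @param ethanol ethanol series, g/L.
#' @param substrate optional substrate series, g/L, or `NULL`.
#' @return an object of class `"timecourse"`.
#' @export
timecourse <- function(condition, times, biomass, ethanol, substrate = NULL) {
  structure(list(condition = condition,
                 times = as.numeric(times),
                 biomass = as.numeric(biomass),
                 ethanol = as.numeric(ethanol),
                 substrate = if (is.null(substrate)) NULL else as.numeric(substrate)),
            class = "timecourse")
}

#' Validate a time course against the data-model invariants
#'
#' Checks the structural invariants (times strictly increasing from 0, at
#' least 3 points, equal series lengths, finite non-negative concentrations)
#' and the condition invariants (positive initial substrate, pH in 0--14,
#' non-negative molar salinity). Violations are returned, not raised.
#'
#' @param tc a [timecourse()].
#' @return character vector of violation descriptions (empty when valid).
#' @export
validate_timecourse <- function(tc) {
  v <- character(0)
  cd <- tc$condition
  if (!is.finite(cd$s_g0) || cd$s_g0 <= 0) {
    v <- c(v, sprintf("condition.s_g0: must be > 0 (got %s)", cd$s_g0))
  }
  if (!is.na(cd$ph) && (cd$ph < 0 || cd$ph > 14)) {
    v <- c(v, sprintf("condition.ph: must lie in [0, 14] (got %s)", cd$ph))
  }
  m <- tryCatch(salinity_to_molar(cd$salinity), error = function(e) NA_real_)
  if (is.na(m)) {
    v <- c(v, sprintf("condition.salinity: unrecognized value '%s'", cd$salinity))
  } else if (m < 0) {
    v <- c(v, sprintf("condition.salinity: molar value must be >= 0 (got %s)", m))
  }
  if (!is.finite(cd$replicate) || cd$replicate < 1) {
    v <- c(v, "condition.replicate: must be a positive integer")
  }

  n <- length(tc$times)
  if (n < 3) {
    v <- c(v, sprintf("times: at least 3 sampling points required (got %d)", n))
  }
  if (n >= 1 && tc$times[1] != 0) {
    v <- c(v, sprintf("times: first sampling time must be 0 (got %s)", tc$times[1]))
  }
  if (n >= 2) {
    bad <- which(diff(tc$times) <= 0)
    for (i in bad) {
      v <- c(v, sprintf("times: not strictly increasing at index %d", i + 1L))
    }
  }
  series <- list(biomass = tc$biomass, ethanol = tc$ethanol)
  if (!is.null(tc$substrate)) series$substrate <- tc$substrate
  for (nm in names(series)) {
    x <- series[[nm]]
    if (length(x) != n) {
      v <- c(v, sprintf("%s: length %d does not match times length %d",
                        nm, length(x), n))
      next
    }
    bad <- which(!is.finite(x) | x < 0)
    for (i in bad) {
      v <- c(v, sprintf("%s: non-finite or negative value at index %d", nm, i))
    }
  }
  v
}

assert_valid_timecourse <- function(tc) {
  v <- validate_timecourse(tc)
  if (length(v)) {
    stop_classed("fermkin_validation_error",
                 "invalid time course for '%s' (replicate %d): %s",
                 tc$condition$condition_id, tc$condition$replicate,
                 paste(v, collapse = "; "))
  }
  invisible(tc)
}

#' @export
print.timecourse <- function(x, ...) {
  cd <- x$condition
  cat(sprintf("<timecourse> %s (rep %d): %s, s0 = %g g/L, salinity = %s, pH = %g\n",
              cd$condition_id, cd$replicate, cd$carbon_source, cd$s_g0,
              cd$salinity, cd$ph))
  cat(sprintf("  %d samples over [0, %g] h; substrate %s\n",
              length(x$times), max(x$times),
              if (is.null(x$substrate)) "absent" else "present"))
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  cd <- x$condition
  data.frame(condition_id = cd$condition_id,
             carbon_source = cd$carbon_source,
             s_g0_g_per_L = cd$s_g0,
             salinity = cd$salinity,
             ph = cd$ph,
             replicate = cd$replicate,
             time_h = x$times,
             biomass_g_per_L = x$biomass,
             ethanol_g_per_L = x$ethanol,
             glucose_g_per_L = if (is.null(x$substrate)) NA_real_ else x$substrate,
             stringsAsFactors = FALSE)
}
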