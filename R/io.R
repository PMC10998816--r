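# Long ("tidy") single-file delimited layout: one row per (record, timepoint),
# condition metadata repeated per row. Comma-separated, UTF-8, "." decimal.

.required_cols <- c("condition_id", "carbon_source", "s_g0_g_per_L", "salinity",
                    "ph", "replicate", "time_h", "biomass_g_per_L",
                    "ethanol_g_per_L")

#' Read batch time courses from a delimited file
#'
#' Reads the long-format CSV (header: `condition_id, carbon_source,
#' s_g0_g_per_L, salinity, ph, replicate, time_h, biomass_g_per_L,
#' ethanol_g_per_L[, glucose_g_per_L]`) and returns one [timecourse()] per
#' distinct `(condition_id, replicate)` pair, rows sorted by time within each
#' group. The substrate series is marked absent when the `glucose_g_per_L`
#' column is missing.
#'
#' @param path path to an existing CSV file.
#' @return list of `timecourse` objects.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) {
    stop_classed("fermkin_io_error", "file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(salinity = "character"))
  missing <- setdiff(.required_cols, names(df))
  if (length(missing)) {
    stop_classed("fermkin_format_error",
                 "missing required column%s: %s",
                 if (length(missing) > 1) "s" else "",
                 paste(missing, collapse = ", "))
  }
  has_substrate <- "glucose_g_per_L" %in% names(df)
  if (nrow(df) == 0) return(list())

  conc_cols <- c("biomass_g_per_L", "ethanol_g_per_L",
                 if (has_substrate) "glucose_g_per_L")
  for (col in conc_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop_classed("fermkin_validation_error",
                   "negative concentration in column %s at row %d",
                   col, bad[1])
    }
  }

  key <- paste(df$condition_id, df$replicate, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    g <- g[order(g$time_h), , drop = FALSE]
    if (any(diff(g$time_h) <= 0)) {
      stop_classed("fermkin_validation_error",
                   "non-increasing time values within group (condition_id = '%s', replicate = %s)",
                   g$condition_id[1], g$replicate[1])
    }
    timecourse(
      condition = condition(g$condition_id[1], g$carbon_source[1],
                            g$s_g0_g_per_L[1], g$salinity[1], g$ph[1],
                            g$replicate[1]),
      times = g$time_h,
      biomass = g$biomass_g_per_L,
      ethanol = g$ethanol_g_per_L,
      substrate = if (has_substrate && !all(is.na(g$glucose_g_per_L)))
        g$glucose_g_per_L else NULL
    )
  }) |> unname()
}

#' Write batch time courses to a delimited file
#'
#' Inverse of [read_timecourses()]: writes the long format with one row per
#' `(record, timepoint)`. Numeric fields are rendered at full (17 significant
#' digit) precision so that a write/read round trip reproduces every value
#' bit-for-bit. An empty collection yields a header-only file.
#'
#' @param records list of [timecourse()] objects (all must be valid).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(records, path) {
  for (tc in records) assert_valid_timecourse(tc)
  any_substrate <- any(vapply(records, function(tc) !is.null(tc$substrate),
                              logical(1)))
  header <- c(.required_cols, if (any_substrate) "glucose_g_per_L")
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) {
                    stop_classed("fermkin_io_error", "cannot write to %s: %s",
                                 path, conditionMessage(e))
                  })
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (tc in records) {
    cd <- tc$condition
    n <- length(tc$times)
    sub <- if (is.null(tc$substrate)) rep(NA_real_, n) else tc$substrate
    rows <- paste(cd$condition_id, cd$carbon_source, format_full(cd$s_g0),
                  cd$salinity, format_full(cd$ph), cd$replicate,
                  format_full(tc$times), format_full(tc$biomass),
                  format_full(tc$ethanol), sep = ",")
    if (any_substrate) rows <- paste(rows, format_full(sub), sep = ",")
    writeLines(rows, con)
  }
  invisible(path)
}
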