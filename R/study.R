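# End-to-end study driver: generation -> descriptors -> Monod fits ->
# comparison tables, with a manifest for reproducibility.

#' Assemble and validate a study configuration
#'
#' A study mirrors the usual one-factor-at-a-time optimization sequence:
#' an initial-substrate gradient, a pH gradient and a salinity gradient, each
#' run at the base values of the other two factors, with a common replicate
#' count, noise level and master seed.
#'
#' @param params a [sim_params()] object (or a named list of overrides of the
#'   default preset).
#' @param stress a [stress_params()] object (or named list of overrides).
#' @param s0_grid initial substrate levels, g/L.
#' @param ph_grid pH levels.
#' @param salinity_grid salinity values (molar or labels).
#' @param base named list with the base `s0`, `ph`, `salinity` used for the
#'   axes not being varied.
#' @param replicates replicates per condition (>= 1).
#' @param seed integer master seed (required: no silent nondeterminism).
#' @param alpha significance level of the comparison layer.
#' @param fit_which which specific rates to fit over the s0 grid.
#' @param out_dir output directory for [run_study()].
#' @return an object of class `"study_config"`.
#' @export
study_config <- function(params = sim_params(), stress = stress_params(),
                         s0_grid = c(50, 75, 100, 125, 150, 175, 200, 225, 250),
                         ph_grid = seq(3, 7, by = 0.5),
                         salinity_grid = c("distilled", "half_seawater",
                                           "seawater", "1", "2", "3", "4"),
                         base = list(s0 = 175, ph = 5.5, salinity = "seawater"),
                         replicates = 3L, seed, alpha = 0.05,
                         fit_which = c("growth", "production"),
                         out_dir = "results/study") {
  if (missing(seed) || is.null(seed)) {
    stop_classed("fermkin_config_error",
                 "study_config requires an explicit seed")
  }
  if (is.list(params) && !inherits(params, "sim_params")) {
    params <- do.call(sim_params, params)
  }
  if (is.list(stress) && !inherits(stress, "stress_params")) {
    stress <- do.call(stress_params, stress)
  }
  stopifnot(length(s0_grid) >= 1, length(ph_grid) >= 1,
            length(salinity_grid) >= 1, replicates >= 1,
            all(fit_which %in% c("growth", "production")))
  structure(list(params = params, stress = stress,
                 s0_grid = as.numeric(s0_grid), ph_grid = as.numeric(ph_grid),
                 salinity_grid = as.character(salinity_grid),
                 base = base, replicates = as.integer(replicates),
                 seed = as.integer(seed), alpha = alpha,
                 fit_which = fit_which, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a JSON file
#'
#' @param path path to a JSON file whose keys match [study_config()]
#'   arguments.
#' @return a `"study_config"` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    stop_classed("fermkin_io_error", "config file not found: %s", path)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(study_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

.compare_metrics <- c("e_p", "x_m", "y_ps", "y_xs", "q_p", "q_s", "v_g", "mu")

comparison_table <- function(desc, alpha) {
  reps <- desc[desc$row_type == "replicate", ]
  out <- list()
  for (metric in .compare_metrics) {
    vals <- reps[[metric]]
    if (all(is.na(vals))) next
    groups <- split(vals, factor(reps$condition_id,
                                 levels = unique(reps$condition_id)))
    th <- tryCatch(tukey_hsd(groups, alpha), error = function(e) NULL)
    letters_out <- if (is.null(th)) NA_character_ else compact_letters(th)
    for (g in names(groups)) {
      out[[length(out) + 1]] <- data.frame(
        metric = metric, condition_id = g,
        mean = mean(groups[[g]]), sd = stats::sd(groups[[g]]),
        n = length(groups[[g]]),
        letters = if (is.null(th)) NA_character_ else unname(letters_out[g]),
        f_stat = if (is.null(th)) NA_real_ else th$anova$f_stat,
        p_value = if (is.null(th)) NA_real_ else th$anova$p_value,
        alpha = alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Render a descriptor comparison in rows-as-parameters orientation
#'
#' Formats the long comparison table of [run_study()] the way bioprocess
#' descriptor tables are usually printed: one row per descriptor, one column
#' per condition, cells `mean +/- sd^letters` at 4 significant figures.
#'
#' @param comparison long comparison data.frame (`metric`, `condition_id`,
#'   `mean`, `sd`, `letters`).
#' @return character matrix (rows = descriptors, columns = conditions).
#' @export
render_comparison <- function(comparison) {
  metrics <- unique(comparison$metric)
  conds <- unique(comparison$condition_id)
  m <- matrix("", length(metrics), length(conds),
              dimnames = list(metrics, conds))
  for (i in seq_len(nrow(comparison))) {
    row <- comparison[i, ]
    m[row$metric, row$condition_id] <-
      sprintf("%.4g ± %.2g%s", row$mean, row$sd,
              if (is.na(row$letters)) "" else paste0("^", row$letters))
  }
  m
}

#' Run a full simulated optimization study
#'
#' Executes the whole pipeline for each design axis (initial substrate, pH,
#' salinity): generates replicate time courses, computes descriptor tables,
#' fits the Monod model to the replicate-averaged specific growth and
#' production rates over the substrate gradient, builds Tukey
#' letter-comparison tables and identifies the optimum per axis, and writes
#' every artifact plus a JSON run manifest (config hash, seed, package
#' version, artifact list) under `config$out_dir`. Identical configurations
#' give byte-identical numeric outputs. With `replicates = 1` the comparison
#' stage is skipped with a warning (no within-group variance).
#'
#' @param config a [study_config()].
#' @return invisibly, a list with the generated records, descriptor tables,
#'   Monod fits, comparison tables, optima and the manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  stage <- "setup"

  result <- list(records = list(), descriptors = list(), fits = list(),
                 comparisons = list(), optima = list())
  write_manifest <- function(error = NULL) {
    manifest <- list(package = "fermkin",
                     version = as.character(utils::packageVersion("fermkin")),
                     seed = config$seed,
                     config_md5 = config_hash(config),
                     artifacts = artifacts,
                     error = error)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    manifest
  }

  axes <- list(
    substrate = list(s0 = config$s0_grid, ph = config$base$ph,
                     sal = config$base$salinity),
    ph = list(s0 = config$base$s0, ph = config$ph_grid,
              sal = config$base$salinity),
    salinity = list(s0 = config$base$s0, ph = config$base$ph,
                    sal = config$salinity_grid))

  tryCatch({
    for (axis in names(axes)) {
      stage <- paste0("generate_", axis)
      ax <- axes[[axis]]
      recs <- generate_study(config$params, config$stress,
                             s0_grid = ax$s0, ph_grid = ax$ph,
                             salinity_grid = ax$sal,
                             replicates = config$replicates,
                             seed = derive_seed(config$seed, stage_key(axis)))
      result$records[[axis]] <- recs
      path <- file.path(config$out_dir, sprintf("timecourses_%s.csv", axis))
      write_timecourses(recs, path)
      artifacts <- c(artifacts, basename(path))

      stage <- paste0("descriptors_", axis)
      desc <- descriptor_table(recs)
      result$descriptors[[axis]] <- desc
      path <- file.path(config$out_dir, sprintf("descriptors_%s.csv", axis))
      utils::write.csv(desc, path, row.names = FALSE)
      artifacts <- c(artifacts, basename(path))
    }

    stage <- "monod_fits"
    fit_rows <- list()
    for (wh in config$fit_which) {
      pts <- rate_vs_substrate(result$records$substrate, wh)
      fit <- fit_monod(pts)
      result$fits[[wh]] <- fit
      fit_rows[[wh]] <- data.frame(
        which = wh, rate_max = fit$rate_max, ks = fit$ks, r2 = fit$r2,
        sse = fit$sse, n = fit$n, converged = fit$converged,
        se_rate_max = fit$se_rate_max, se_ks = fit$se_ks)
    }
    path <- file.path(config$out_dir, "monod_fits.csv")
    utils::write.csv(do.call(rbind, fit_rows), path, row.names = FALSE)
    artifacts <- c(artifacts, basename(path))

    stage <- "comparison"
    if (config$replicates < 2) {
      warning("comparison stage skipped: replicates = 1 gives no within-group variance",
              call. = FALSE)
    } else {
      optimum_metric <- c(substrate = "e_p", ph = "e_p", salinity = "y_ps")
      opt_rows <- list()
      for (axis in names(axes)) {
        cmp <- comparison_table(result$descriptors[[axis]], config$alpha)
        result$comparisons[[axis]] <- cmp
        path <- file.path(config$out_dir, sprintf("comparison_%s.csv", axis))
        utils::write.csv(cmp, path, row.names = FALSE)
        artifacts <- c(artifacts, basename(path))

        opt <- find_optimum(result$descriptors[[axis]],
                            optimum_metric[[axis]], config$alpha)
        result$optima[[axis]] <- opt
        opt_rows[[axis]] <- data.frame(
          axis = axis, metric = opt$metric,
          best_condition = opt$best_condition, best_mean = opt$best_mean,
          co_optimal = paste(opt$co_optimal, collapse = ";"))
      }
      path <- file.path(config$out_dir, "optima.csv")
      utils::write.csv(do.call(rbind, opt_rows), path, row.names = FALSE)
      artifacts <- c(artifacts, basename(path))
    }

    stage <- "manifest"
    result$manifest <- write_manifest()
  }, error = function(e) {
    write_manifest(error = list(stage = stage, message = conditionMessage(e)))
    stop_classed("fermkin_study_error", "stage '%s' failed: %s",
                 stage, conditionMessage(e))
  })
  invisible(result)
}
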