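# Statistical comparison layer: one-way ANOVA, Tukey HSD pairwise
# comparisons, compact letter displays, optimum identification.

as_group_list <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' One-way analysis of variance across replicate groups
#'
#' Standard one-way decomposition (via `stats::lm`/`stats::anova`), with the
#' omnibus F statistic and p-value from the F distribution.
#'
#' @param groups named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 values; within-group variance must not be all zero).
#' @return list with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `ms_within`, and per-group `n` and `means`.
#' @export
anova_oneway <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) {
    stop_classed("fermkin_data_error", "anova_oneway needs at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop_classed("fermkin_data_error",
                 "group '%s' has fewer than 2 replicate values",
                 names(groups)[which(sizes < 2)[1]])
  }
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) {
    stop_classed("fermkin_degenerate_error",
                 "all values identical: variance is degenerate")
  }
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (within_ss == 0) {
    stop_classed("fermkin_degenerate_error",
                 "within-group variance is zero in every group: F is undefined")
  }
  df <- data.frame(
    value = values,
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  a <- stats::anova(stats::lm(value ~ group, data = df))
  list(f_stat = a$`F value`[1],
       df_between = a$Df[1], df_within = a$Df[2],
       p_value = a$`Pr(>F)`[1],
       ms_within = a$`Mean Sq`[2],
       n = sizes,
       means = vapply(groups, mean, numeric(1)))
}

#' Tukey HSD all-pairs comparison
#'
#' For each pair of groups the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSW * (1/n_i + 1/n_j) / 2)`
#' (the Tukey--Kramer harmonic form, reducing to the classical statistic for
#' balanced groups) is compared with the critical value of the studentized
#' range distribution at `(k, df_within, alpha)`, evaluated numerically via
#' `qtukey`/`ptukey`.
#'
#' @param groups named list of numeric replicate vectors (as
#'   [anova_oneway()]).
#' @param alpha family-wise significance level, in (0, 0.5].
#' @return object of class `"tukey_hsd"`: matrices `q`, `p_value`,
#'   `significant`, plus `crit`, `alpha`, group `means`, and the `anova`
#'   results.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 0.5)
  groups <- as_group_list(groups)
  a <- anova_oneway(groups)
  k <- length(groups)
  nm <- names(groups)
  qm <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(a$ms_within * (1 / a$n[i] + 1 / a$n[j]) / 2)
      qm[i, j] <- qm[j, i] <- abs(a$means[i] - a$means[j]) / se
    }
  }
  crit <- stats::qtukey(1 - alpha, k, a$df_within)
  pm <- stats::ptukey(qm, k, a$df_within, lower.tail = FALSE)
  diag(pm) <- 1
  sig <- qm > crit
  diag(sig) <- FALSE
  structure(list(q = qm, p_value = pm, significant = sig, crit = crit,
                 alpha = alpha, means = a$means, n = a$n, anova = a),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("<tukey_hsd> %d groups, alpha = %g, q_crit = %.4f\n",
              length(x$means), x$alpha, x$crit))
  cl <- compact_letters(x$significant, x$means)
  df <- data.frame(mean = x$means, n = x$n, letters = cl[names(x$means)])
  print(df[order(-df$mean), ])
  invisible(x)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: starting from the single class of all
#' groups, every significant pair splits each class containing both members,
#' and classes that become subsets of others are absorbed. Two groups share
#' at least one letter if and only if their comparison is non-significant.
#' Letters are assigned to classes in descending order of their highest
#' group mean, so the top class is lettered `a`.
#'
#' @param significant symmetric logical matrix (dimnames = group labels);
#'   `TRUE` marks a significantly different pair. A `"tukey_hsd"` object is
#'   also accepted.
#' @param means named numeric group means (used for letter ordering; taken
#'   from the `tukey_hsd` object when omitted).
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(significant, means = NULL) {
  if (inherits(significant, "tukey_hsd")) {
    means <- means %||% significant$means
    significant <- significant$significant
  }
  stopifnot(is.matrix(significant), nrow(significant) == ncol(significant),
            !is.null(rownames(significant)))
  nm <- rownames(significant)
  if (is.null(means)) means <- stats::setNames(rep(0, length(nm)), nm)

  classes <- list(nm)
  for (i in seq_len(length(nm) - 1)) {
    for (j in (i + 1):length(nm)) {
      if (!significant[i, j]) next
      gi <- nm[i]; gj <- nm[j]
      new_classes <- list()
      for (cl in classes) {
        if (gi %in% cl && gj %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, gi)),
                           list(setdiff(cl, gj)))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      # absorb classes that are subsets of another
      keep <- rep(TRUE, length(new_classes))
      for (u in seq_along(new_classes)) {
        for (v in seq_along(new_classes)) {
          if (u != v && keep[u] &&
              all(new_classes[[u]] %in% new_classes[[v]]) &&
              (length(new_classes[[u]]) < length(new_classes[[v]]) || u > v)) {
            keep[u] <- FALSE
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  classes <- classes[lengths(classes) > 0]
  # order classes by descending top member mean (ties: by member names)
  ord <- order(-vapply(classes, function(cl) max(means[cl]), numeric(1)),
               vapply(classes, function(cl) paste(sort(cl), collapse = ","),
                      character(1)))
  classes <- classes[ord]
  if (length(classes) > 26) {
    stop_classed("fermkin_data_error",
                 "more than 26 letter classes are not supported")
  }
  out <- stats::setNames(rep("", length(nm)), nm)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' Identify the optimal condition for a descriptor
#'
#' Finds the condition with the highest replicate-mean value of `metric` in a
#' [descriptor_table()] and, when replicate data allow a Tukey comparison,
#' the set of co-optimal conditions (all conditions sharing a letter with the
#' best one).
#'
#' @param table a [descriptor_table()] data.frame.
#' @param metric descriptor column name (e.g. `"e_p"`, `"y_ps"`).
#' @param alpha significance level for the letter display.
#' @return list with `metric`, `best_condition`, `best_mean`, `letters`
#'   (named vector or `NULL` when not computable), and `co_optimal`.
#' @export
find_optimum <- function(table, metric, alpha = 0.05) {
  if (!metric %in% names(table)) {
    stop_classed("fermkin_data_error", "unknown descriptor metric '%s'", metric)
  }
  reps <- table[table$row_type == "replicate", ]
  groups <- split(reps[[metric]], factor(reps$condition_id,
                                         levels = unique(reps$condition_id)))
  if (length(groups) < 2) {
    stop_classed("fermkin_data_error",
                 "find_optimum needs at least 2 conditions")
  }
  means <- vapply(groups, mean, numeric(1))
  best <- names(means)[which.max(means)]
  letters_out <- NULL
  co_optimal <- best
  if (all(lengths(groups) >= 2)) {
    th <- tryCatch(tukey_hsd(groups, alpha), error = function(e) NULL)
    if (!is.null(th)) {
      letters_out <- compact_letters(th)
      shared <- vapply(names(means), function(g) {
        any(strsplit(letters_out[g], "")[[1]] %in%
              strsplit(letters_out[best], "")[[1]])
      }, logical(1))
      co_optimal <- names(means)[shared]
    } else {
      # degenerate variance (e.g. noise-free replicates): ties by equal mean
      co_optimal <- names(means)[means == max(means)]
    }
  }
  list(metric = metric, best_condition = best, best_mean = max(means),
       means = means, letters = letters_out, co_optimal = co_optimal)
}
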