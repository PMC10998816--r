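#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a parent seed and integer keys
#'
#' Counter-based linear-congruential mixing so that every cell/replicate of a
#' study, and every stage of a run, draws from its own deterministic stream.
#' The result is always a non-negative 32-bit integer.
#'
#' @param seed parent integer seed.
#' @param ... additional integer keys (cell index, replicate index, stage key).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) {
    # products stay < 2^53, so double arithmetic is exact here
    s <- (s * 69069 + (p %% 2147483629) * 101 + 1) %% 2147483629
  }
  as.integer(s)
}

#' Integer key for a stage name (for stage-scoped seed derivation)
#' @param stage character scalar.
#' @return integer.
#' @keywords internal
stage_key <- function(stage) {
  sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1000003L
}

stop_classed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "fermkin_error")))
}

format_full <- function(x) {
  # full round-trip precision for delimited output
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
}
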