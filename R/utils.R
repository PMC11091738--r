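# Internal helpers: condition classes, number formatting, small shared utilities.

# Condition hierarchy: every package error is a `retree_error`; the subclass
# determines the CLI exit code and lets callers distinguish configuration,
# format, data, structural, parse, version, input, not-applicable and
# degenerate-split failures.
retree_abort <- function(message, class) {
  cond <- structure(
    class = c(paste0("retree_", class, "_error"), "retree_error",
              "error", "condition"),
    list(message = message, call = NULL)
  )
  stop(cond)
}

stop_config     <- function(msg) retree_abort(msg, "config")
stop_format     <- function(msg) retree_abort(msg, "format")
stop_data       <- function(msg) retree_abort(msg, "data")
stop_structural <- function(msg) retree_abort(msg, "structural")
stop_parse      <- function(msg) retree_abort(msg, "parse")
stop_input      <- function(msg) retree_abort(msg, "input")
stop_version    <- function(msg) retree_abort(msg, "version")
stop_not_applicable <- function(msg) retree_abort(msg, "not_applicable")
stop_degenerate <- function(msg) retree_abort(msg, "degenerate_split")

# Shortest decimal representation of a double that round-trips exactly.
# Used everywhere a number is rendered (test strings, JSON export) so that
# render/parse and export/import cycles are byte-stable.
fmt_num <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) stop_input("cannot format NA as a number")
    if (xi == floor(xi) && abs(xi) < 1e15) {
      s <- sprintf("%.0f", xi)
      if (as.numeric(s) == xi) return(s)
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, xi)
      if (as.numeric(s) == xi) return(s)
    }
    sprintf("%.17g", xi)
  }, character(1))
}

# Score-comparison tolerance: gain-ratio / info-gain differences at or below
# this are treated as ties so the canonical tie-break (family, attribute
# index, threshold) is stable against last-ulp floating noise.
SCORE_TOL <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a
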