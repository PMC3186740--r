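#' @keywords internal
"_PACKAGE"

# Structured logging to stderr. Silenced package-wide with
# options(tissueconcord.quiet = TRUE) or per-call via the exported helpers.
tc_log <- function(fmt, ...) {
  if (isTRUE(getOption("tissueconcord.quiet", FALSE))) return(invisible(NULL))
  message("[tissueconcord] ", sprintf(fmt, ...))
  invisible(NULL)
}

#' Silence or restore package log messages
#'
#' The package reports dropped probesets, collapsed duplicate edges and
#' similar bookkeeping on stderr. `quiet_logging(TRUE)` turns these messages
#' off for the session.
#'
#' @param quiet Logical; `TRUE` silences log messages.
#' @return The previous setting, invisibly.
#' @export
quiet_logging <- function(quiet = TRUE) {
  old <- getOption("tissueconcord.quiet", FALSE)
  options(tissueconcord.quiet = isTRUE(quiet))
  invisible(old)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic stream splitting: one user-facing seed governs all stages.
# Sub-seeds are derived with a fixed multiplicative hash per named stream so
# each stage is independently reproducible; results stay < 2^31.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_tc("'%s' must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}
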