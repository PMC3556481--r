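# Condition helpers. Two error classes drive the CLI exit-code contract:
# validation errors (bad input, exit 2) and computation errors (a fit or
# numeric routine failed, exit 3).

stop_gf <- function(message, class) {
  cond <- structure(
    class = c(class, "glycoforge_error", "error", "condition"),
    list(message = message, call = sys.call(-2))
  )
  stop(cond)
}

stop_validation <- function(fmt, ...) {
  stop_gf(sprintf(fmt, ...), "glycoforge_validation_error")
}

stop_computation <- function(fmt, ...) {
  stop_gf(sprintf(fmt, ...), "glycoforge_computation_error")
}

#' Emit a structured log line on stderr
#'
#' Line-oriented logging used by the command-line interface. Messages go to
#' stderr so stdout stays clean for data streams. Verbosity is controlled by
#' `options(glycoforge.verbosity = )`: 0 silences `info`, 1 (default) prints
#' `info` and `warn`, `error` always prints.
#'
#' @param level one of "info", "warn", "error"
#' @param module short module tag (e.g. "enumeration")
#' @param msg message text
#' @return invisibly, the formatted line
#' @export
gf_log <- function(level = c("info", "warn", "error"), module, msg) {
  level <- match.arg(level)
  verbosity <- getOption("glycoforge.verbosity", 1L)
  show <- switch(level,
    info  = verbosity >= 1L,
    warn  = verbosity >= 1L,
    error = TRUE
  )
  line <- sprintf("[%s] %s: %s", level, module, msg)
  if (show) message(line)
  invisible(line)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all simulation entry points free of hidden global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
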