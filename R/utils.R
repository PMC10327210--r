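# Internal helpers shared across modules.

.LOG_LEVELS <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set the package log level
#'
#' Pipeline stages log their inputs, parameter sets and seeds at INFO level.
#'
#' @param level one of "DEBUG", "INFO", "WARN", "ERROR".
#' @return The previous level, invisibly.
#' @export
setLogLevel <- function(level = c("INFO", "DEBUG", "WARN", "ERROR")) {
  level <- match.arg(level)
  old <- getOption("rpntools.loglevel", "WARN")
  options(rpntools.loglevel = level)
  invisible(old)
}

.log <- function(level, fmt, ...) {
  cur <- getOption("rpntools.loglevel", "WARN")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cur]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# deterministic RNG scope: run expr under a seed, restore RNG state after
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
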