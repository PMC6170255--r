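# Classed conditions so callers (and the CLI) can distinguish bad input from
# bad files from everything else.

abort_validation <- function(msg, ..., data = NULL) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("kinsel_validation_error", "kinsel_error"),
                      data = data))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("kinsel_io_error", "kinsel_error")))
}

warn_kinsel <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "kinsel_warning"),
          call. = FALSE)
}

#' Log a timestamped message to standard error
#'
#' Used by the command-line interface; controlled by the `kinsel.verbosity`
#' option (0 = quiet, 1 = normal, 2 = verbose).
#'
#' @param msg Message (sprintf template).
#' @param ... Values interpolated into `msg`.
#' @param level Minimum verbosity at which the message is emitted.
#' @return Invisibly, the formatted line.
#' @export
log_msg <- function(msg, ..., level = 1L) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(msg, ...))
  if (getOption("kinsel.verbosity", 1L) >= level) {
    cat(line, "\n", sep = "", file = stderr())
  }
  invisible(line)
}
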