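# Internal condition constructors. Every user-facing failure is signalled as a
# classed condition so callers (and the CLI) can map failure kinds to exit
# behaviour without string matching.

.gmatStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "gmat_error", "error")))
}

.formatError    <- function(fmt, ...) .gmatStop("gmat_format_error", fmt, ...)
.validationError <- function(fmt, ...) .gmatStop("gmat_validation_error", fmt, ...)
.parameterError <- function(fmt, ...) .gmatStop("gmat_parameter_error", fmt, ...)
.alignmentError <- function(fmt, ...) .gmatStop("gmat_alignment_error", fmt, ...)
.singularError  <- function(fmt, ...) .gmatStop("gmat_singular_error", fmt, ...)
.usageError     <- function(fmt, ...) .gmatStop("gmat_usage_error", fmt, ...)
.ioError        <- function(fmt, ...) .gmatStop("gmat_io_error", fmt, ...)
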