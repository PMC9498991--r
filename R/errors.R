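# Classed conditions used across the package.  Every user-facing error is an
# "rs_error" so callers (and the command-line wrapper) can map failures to
# exit codes without string matching.

rs_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rs_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_format       <- function(msg) rs_abort(msg, "rs_format_error")
abort_validation   <- function(msg) rs_abort(msg, "rs_validation_error")
abort_parameter    <- function(msg) rs_abort(msg, "rs_parameter_error")
abort_data         <- function(msg) rs_abort(msg, "rs_data_error")
abort_domain       <- function(msg) rs_abort(msg, "rs_domain_error")
abort_missing_data <- function(msg) rs_abort(msg, "rs_missing_data_error")
abort_insufficient <- function(msg) rs_abort(msg, "rs_insufficient_data_error")
abort_degenerate   <- function(msg) rs_abort(msg, "rs_degenerate_data_error")
abort_model        <- function(msg) rs_abort(msg, "rs_model_error")
abort_fit          <- function(msg) rs_abort(msg, "rs_fit_error")
abort_io           <- function(msg) rs_abort(msg, "rs_io_error")
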