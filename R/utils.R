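# Classed conditions so callers can distinguish bad parameters from bad data
# from I/O problems programmatically.
abort_invalid_parameter <- function(msg, ...) {
  abort(msg, class = "zfcardio_invalid_parameter", ...)
}

abort_invalid_input <- function(msg, ...) {
  abort(msg, class = "zfcardio_invalid_input", ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = "zfcardio_io_error", ...)
}

abort_segmentation <- function(msg, ...) {
  abort(msg, class = "zfcardio_segmentation_error", ...)
}

abort_geometry <- function(msg, ...) {
  abort(msg, class = "zfcardio_geometry_error", ...)
}

abort_cycles <- function(msg, ...) {
  abort(msg, class = "zfcardio_cycle_error", ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = "zfcardio_degenerate_error", ...)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_invalid_parameter(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Microlitre bookkeeping: the printed equations work in micrometres, figures
# report nanolitres. 1 nL = 1e6 um^3.
UM3_PER_NL <- 1e6
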