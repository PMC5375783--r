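# Classed conditions so the pipeline can map failures onto the "unknown"
# outcome without string-matching error messages.

ts_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "thermaseg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_degenerate <- function(message) {
  ts_stop(message, "thermaseg_degenerate_input")
}

# Segmentation failures are recoverable: the pipeline reports "unknown".
stop_segmentation <- function(message) {
  ts_stop(message, "thermaseg_segmentation_failed")
}

is_segmentation_error <- function(e) inherits(e, "thermaseg_segmentation_failed")
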