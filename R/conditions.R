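# Classed conditions so callers (and tests) can distinguish failure modes.

rb_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "reliefbench_error")))
}

abort_invalid <- function(msg) rb_abort(msg, "reliefbench_invalid_parameter")
abort_feasibility <- function(msg) rb_abort(msg, "reliefbench_feasibility_error")
abort_format <- function(msg) rb_abort(msg, "reliefbench_format_error")
abort_degenerate <- function(msg) rb_abort(msg, "reliefbench_degenerate_class")
abort_integrity <- function(msg) rb_abort(msg, "reliefbench_integrity_error")
abort_shape <- function(msg) rb_abort(msg, "reliefbench_shape_error")
abort_orchestration <- function(msg) rb_abort(msg, "reliefbench_orchestration_error")
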