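# Classed conditions so callers (and the CLI) can map failures to exit codes.

stopShape <- function(...) {
  stop(structure(class = c("shearfuse_shape_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopValue <- function(...) {
  stop(structure(class = c("shearfuse_value_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopConfig <- function(...) {
  stop(structure(class = c("shearfuse_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopIO <- function(...) {
  stop(structure(class = c("shearfuse_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

checkFinite <- function(x, what) {
  if (!all(is.finite(x))) stopValue(what, " contains non-finite values")
  invisible(x)
}
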