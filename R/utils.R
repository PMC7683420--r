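# internal validation helpers

stop_wavesel <- function(..., class = "wavesel_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_validation <- function(...) stop_wavesel(..., class = "wavesel_validation_error")
abort_format <- function(...) stop_wavesel(..., class = "wavesel_format_error")

check_finite <- function(x, what) {
  if (!all(is.finite(x))) abort_validation(what, " contains non-finite values")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
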