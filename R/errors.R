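# Error helpers: validation errors (bad arguments/shapes) and I/O errors are
# distinct condition classes so the command-line layer can map them to exit
# codes (2 and 3 respectively).

err_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("emaseg_validation_error", "error", "condition")))
}

err_io <- function(msg) {
  stop(errorCondition(msg, class = c("emaseg_io_error", "error", "condition")))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) err_validation(paste(what, "contains non-finite values"))
  invisible(x)
}
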