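# Classed conditions used across modules so callers (and the pipeline) can
# distinguish "this input is excluded by the analysis rules" from real errors.

gd_stop <- function(msg, class, call. = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "gd_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cnd)
}

#' @noRd
excluded_input <- function(msg) gd_stop(msg, "gd_excluded_input")

#' @noRd
undefined_signal <- function(msg) gd_stop(msg, "gd_undefined")

#' @noRd
unexpressed_signal <- function(msg) gd_stop(msg, "gd_unexpressed")

# precondition helper: fails with the offending field named
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) gd_stop(msg, "gd_invalid_input", call. = sys.call(-2))
  invisible(TRUE)
}
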