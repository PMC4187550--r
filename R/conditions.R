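# Classed error conditions used across the pipeline so callers (and the CLI)
# can distinguish validation problems from runtime failures.

abort_glut4 <- function(message, class, ...) {
  stop(structure(
    class = c(class, "glut4_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warn_glut4 <- function(message, class) {
  warning(structure(
    class = c(class, "glut4_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    abort_glut4(
      sprintf("`%s` must be a finite %snumeric scalar, got %s",
              name, if (positive) "positive " else "", deparse(x)),
      "glut4_invalid_parameter"
    )
  }
  invisible(x)
}
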