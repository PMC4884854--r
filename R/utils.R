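#' @noRd
nlswei_abort <- function(msg, class) {
  stop(structure(class = c(class, "nlswei_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    nlswei_abort(sprintf("non-finite values in %s", what),
                 "nlswei_invalid_input")
  invisible(x)
}

# mm -> m for user-facing geometry arguments
#' @noRd
mm <- function(x) x * 1e-3
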