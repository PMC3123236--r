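#' @keywords internal
stop_pw <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "pw_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

stop_validation <- function(msg, ...) stop_pw("pw_validation_error", msg, ...)
stop_conflict   <- function(msg, ...) stop_pw("pw_conflict_error", msg, ...)
stop_reference  <- function(msg, ...) stop_pw("pw_reference_error", msg, ...)
stop_parse      <- function(msg, position = NA_integer_, ...) {
  stop_pw("pw_parse_error", msg, position = position, ...)
}
stop_permission <- function(msg, ...) stop_pw("pw_permission_error", msg, ...)
stop_io         <- function(msg, ...) stop_pw("pw_io_error", msg, ...)

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop_validation(sprintf("%s must be a non-empty string", what))
  invisible(x)
}
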