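# internal validation helpers: all errors name the offending field so that
# config loading can surface actionable messages

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower) {
    if (x <= lower) stop_field(field, sprintf("must be > %g", lower))
  } else if (x < lower) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  if (strict_upper) {
    if (x >= upper) stop_field(field, sprintf("must be < %g", upper))
  } else if (x > upper) {
    stop_field(field, sprintf("must be <= %g", upper))
  }
  invisible(as.numeric(x))
}

check_choice <- function(x, field, choices) {
  if (length(x) != 1L || !is.character(x) || !(x %in% choices))
    stop_field(field, paste0("must be one of: ", paste(choices, collapse = ", ")))
  invisible(x)
}

check_string <- function(x, field) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || !nzchar(x))
    stop_field(field, "must be a non-empty string")
  invisible(x)
}
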