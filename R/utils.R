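# Internal argument checkers shared across the package.

check_count <- function(x, name, allow_vector = FALSE) {
  if (!allow_vector && length(x) != 1L)
    stop("`", name, "` must be a single value", call. = FALSE)
  if (!is.numeric(x) || anyNA(x))
    stop("`", name, "` must be numeric and non-missing", call. = FALSE)
  if (any(x < 0))
    stop("`", name, "` must be non-negative", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8))
    stop("`", name, "` must be integer-valued", call. = FALSE)
  invisible(round(x))
}

check_fraction <- function(x, name, allow_vector = FALSE) {
  if (!allow_vector && length(x) != 1L)
    stop("`", name, "` must be a single value", call. = FALSE)
  if (!is.numeric(x) || anyNA(x))
    stop("`", name, "` must be numeric and non-missing", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  invisible(x)
}

# Cheap deterministic checksum of a list, used only for run logging.
config_checksum <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251)) %% .Machine$integer.max)
}

log_msg <- function(...) message("[sddicost] ", ...)
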