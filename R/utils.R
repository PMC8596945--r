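# Structured conditions so callers (and the CLI) can distinguish bad inputs
# from numerical failures.

abort_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("escimap_invalid_argument", "escimap_error")))
}

abort_numerical <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("escimap_numerical_error", "escimap_error")))
}

abort_dimension <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("escimap_dimension_error", "escimap_error")))
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort_invalid("`", name, "` must be a single finite number")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    abort_invalid("`", name, "` must be an integer >= ", min, ", got ", x)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  check_scalar_number(x, name)
  if (x <= 0 || x >= 1) {
    abort_invalid("`", name, "` must lie strictly between 0 and 1, got ", x)
  }
  x
}
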