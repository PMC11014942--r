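#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Classed conditions so callers can distinguish configuration problems from
# bad data. All inherit from "nitrosource_error".
ns_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "nitrosource_error"), ...)
}

ns_stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    ns_abort(
      sprintf("`%s` must be finite numeric (got %s).", what,
              paste(utils::head(format(x), 3), collapse = ", ")),
      class = "nitrosource_error_invalid_measurement"
    )
  }
  invisible(x)
}

ns_check_sigma <- function(sigma, what) {
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    ns_abort(sprintf("`%s` must be finite and >= 0.", what),
             class = "nitrosource_error_invalid_uncertainty")
  }
  invisible(sigma)
}

#' Sample types recognised in isotope tables
#'
#' @return Character vector of the four recognised sample types.
#' @export
sample_types <- function() {
  c("sediment", "soil", "lake_water", "snow_atmosphere")
}

# Deterministic child-seed derivation: one child stream per generator call so
# modules reproduce in isolation and jointly. Stays within 32-bit range.
child_seed <- function(seed, k) {
  s <- (as.double(seed) + as.double(k) * 10007) %% (2^31 - 1)
  as.integer(max(1, s))
}
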