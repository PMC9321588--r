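# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_lagcm <- function(msg, class = "lagcm_error") {
  rlang::abort(msg, class = c(class, "lagcm_error"))
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort_lagcm(sprintf("`%s` must be a %s number, got %s",
                        name, if (strict) "positive" else "non-negative",
                        deparse(substitute(x))),
                class = "lagcm_validation_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort_lagcm(sprintf("`%s` must be an integer >= %d", name, min),
                class = "lagcm_validation_error")
  }
  invisible(as.integer(x))
}

# glucose molar mass, g/mol
GLUCOSE_MM <- 180.16

# mass-weighted mean of a per-compartment field
weighted_mean_field <- function(values, weights) {
  sum(values * weights) / sum(weights)
}
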