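# Internal argument checks shared across modules.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (!is.na(x)) {
    if (strict_lower && x <= lower) {
      stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
    }
    if (!strict_lower && x < lower) {
      stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
    }
    if (x > upper) {
      stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
    }
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (is.null(seed)) {
    stop("a `seed` is required: generators never draw from global random state",
         call. = FALSE)
  }
  check_count(seed, "seed")
}

#' Evaluate code with a fixed RNG seed, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}
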