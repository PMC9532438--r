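# Internal helpers: argument validation, condition classes, lognormal noise.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ploidyscope_config_error", "ploidyscope_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ploidyscope_data_error", "ploidyscope_error")))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("`%s` must be a single probability in [0, 1], got %s",
                name, paste(format(x), collapse = ", "))
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok)
    stop_config("`%s` must be a single %s number",
                name, if (strict) "positive" else "non-negative")
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_config("`%s` must be a positive integer", name)
  invisible(as.integer(x))
}

# Probability vector: named, non-negative, sums to 1 within tolerance.
check_prob_vector <- function(p, name, levels = NULL, tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0))
    stop_config("`%s` must be a non-negative numeric vector", name)
  if (!is.null(levels)) {
    if (is.null(names(p)) || !setequal(names(p), levels))
      stop_config("`%s` must be named with exactly: %s",
                  name, paste(levels, collapse = ", "))
    p <- p[levels]
  }
  if (abs(sum(p) - 1) > tol)
    stop_config("`%s` must sum to 1 (got %.10f)", name, sum(p))
  p
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
# cv = 0 degenerates to exactly 1 so noise-free simulations are bit-exact.
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
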