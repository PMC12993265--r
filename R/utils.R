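#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper || (!allow_zero && x == 0))
    abort(sprintf("`%s` = %g is outside its valid range [%g, %g]",
                  name, x, lower, upper))
  invisible(x)
}

#' @noRd
check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  invisible(data)
}

#' Finite differences of a uniformly sampled series
#'
#' Central differences in the interior, one-sided at the end points.
#' @noRd
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) abort("need at least 3 samples for finite differences")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}
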