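# broom-style methods for fitted objects.

#' Tidy a spread-regression fit
#'
#' @param x An `xsmm_spread_fit` object from [spread_regression()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @exportS3Method generics::tidy
#' @export
tidy.xsmm_spread_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "median"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' Glance at a spread-regression fit
#'
#' @inheritParams tidy.xsmm_spread_fit
#' @return A one-row tibble: `r.squared`, `slope`, `intercept`,
#'   `n_positions`.
#' @exportS3Method generics::glance
#' @export
glance.xsmm_spread_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, slope = x$slope,
    intercept = x$intercept, n_positions = x$n_positions
  )
}
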