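#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the history-bias regression
#'
#' @param x A [history_regression()] fit.
#' @param ... Unused.
#' @return One row per model term with `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy history_fit
#' @export
tidy.history_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.history_fit
#' @return `glance()`: a one-row tibble with `r.squared`, `slope`, `p.value`
#'   (slope test), `bias_span` (slope times regressor range, as a fraction of
#'   the output range) and `nobs`.
#' @method glance history_fit
#' @export
glance.history_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, slope = x$slope,
                 p.value = x$p.value, bias_span = x$span,
                 nobs = stats::nobs(x$fit))
}
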