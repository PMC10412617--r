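#' Discrete target distributions over the eight sensory bins
#'
#' The sensory network discretizes the external variable into 8 bins (one per
#' cluster). `bin_distribution()` validates an arbitrary probability vector;
#' `target_distribution()` builds the four canonical shapes used throughout:
#'
#' * `"uniform"`: 1/8 per bin.
#' * `"biased"`: 70% of the mass on bins 1-4 (0.175 each), 30% on bins 5-8.
#' * `"unimodal"`: Binomial(7, 1/2) over bins 1..8 — a symmetric centre-peaked
#'   shape with mean 4.5.
#' * `"bimodal"`: equal mixture of Binomial(3, 1/2) on bins 1-4 and on bins
#'   5-8 — two symmetric modes, overall mean 4.5, so the half-integer probe
#'   i = 4.5 sits at the long-term mean.
#'
#' @param p Numeric vector of probabilities (any length >= 2 for
#'   `bin_distribution`; the canonical shapes have length 8).
#' @param shape One of `"uniform"`, `"biased"`, `"unimodal"`, `"bimodal"`.
#' @param n_bins Number of bins (the sensory network fixes this at 8).
#' @return A named numeric probability vector of class `bin_distribution`.
#' @export
#' @examples
#' target_distribution("bimodal")
bin_distribution <- function(p) {
  p <- as.numeric(p)
  stopifnot(
    "probabilities must be non-negative" = all(p >= 0),
    "need at least two bins" = length(p) >= 2,
    "probabilities must be finite" = all(is.finite(p))
  )
  if (abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must sum to 1 (got ", format(sum(p), digits = 15), ")")
  }
  names(p) <- paste0("bin", seq_along(p))
  structure(p, class = c("bin_distribution", "numeric"))
}

#' @rdname bin_distribution
#' @export
target_distribution <- function(shape = c("uniform", "biased", "unimodal", "bimodal"),
                                n_bins = 8) {
  shape <- match.arg(shape)
  stopifnot("canonical shapes are defined over 8 bins" = n_bins == 8)
  p <- switch(shape,
    uniform  = rep(1 / 8, 8),
    biased   = c(rep(0.175, 4), rep(0.075, 4)),
    unimodal = stats::dbinom(0:7, size = 7, prob = 0.5),
    bimodal  = 0.5 * c(stats::dbinom(0:3, 3, 0.5), stats::dbinom(0:3, 3, 0.5))
  )
  bin_distribution(p / sum(p))
}

#' Cumulative distribution of a bin distribution at half-integer inputs
#'
#' `bin_cdf(p, i)` returns `P(X < i)` for the discrete variable X on bins
#' `1..length(p)`. For half-integer `i` this equals `P(X <= floor(i))`.
#'
#' @param p A `bin_distribution` (or probability vector).
#' @param i Evaluation points.
#' @return Numeric vector of CDF values.
#' @export
bin_cdf <- function(p, i) {
  p <- as.numeric(p)
  cum <- c(0, cumsum(p))
  k <- pmin(pmax(floor(i), 0), length(p))
  cum[k + 1L]
}

#' Draw i.i.d. samples from a bin distribution
#'
#' @param p A `bin_distribution`.
#' @param n Number of samples.
#' @return Integer vector of bin indices in `1..length(p)`.
#' @export
draw_samples <- function(p, n) {
  sample.int(length(p), size = n, replace = TRUE, prob = as.numeric(p))
}
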