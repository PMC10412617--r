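#' Decode the active cluster from a spike record
#'
#' Bins the excitatory spikes of one population on the simulation grid,
#' convolves each cluster's spike count with a Gaussian of width (sd)
#' `sigma` ms (symmetric, truncated at 4 sigma, renormalized at the edges),
#' averages over the neurons of the cluster, and takes the per-step argmax.
#' Exact ties — including stretches with no spikes at all — keep the previous
#' label (hysteresis), which avoids spurious switch counts.
#'
#' @param spikes Spike tibble (`population`, `neuron`, `t_ms`) as returned by
#'   the simulation functions.
#' @param population Which population to decode.
#' @param n_clusters Number of clusters in that population.
#' @param neurons_per_cluster Excitatory cluster size (neuron ids
#'   `1..n_clusters*neurons_per_cluster` are the clustered E cells).
#' @param t_start,t_end Decoding window (ms).
#' @param dt Grid step (ms).
#' @param sigma Gaussian smoothing width (ms).
#' @return A tibble of class `decoded_trace` with columns `t_ms` (step ends)
#'   and `label` (active cluster index).
#' @export
active_cluster_trace <- function(spikes, population = "sensory",
                                 n_clusters = 8, neurons_per_cluster = 100,
                                 t_start = NULL, t_end = NULL,
                                 dt = 0.1, sigma = 20) {
  sp <- spikes[spikes$population == population &
                 spikes$neuron <= n_clusters * neurons_per_cluster, ]
  if (nrow(sp) == 0) stop("no excitatory spikes to decode in population '",
                          population, "'")
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_end)) t_end <- max(sp$t_ms)
  sp <- sp[sp$t_ms > t_start + 1e-9 & sp$t_ms <= t_end + 1e-9, ]
  n_steps <- round((t_end - t_start) / dt)
  if (n_steps < 1) stop("decoding window is empty")
  step <- pmin(pmax(ceiling((sp$t_ms - t_start) / dt - 1e-9), 1L), n_steps)
  cl <- (sp$neuron - 1L) %/% neurons_per_cluster + 1L

  counts <- matrix(0, n_steps, n_clusters)
  if (nrow(sp)) {
    tab <- table(factor(step, levels = seq_len(n_steps)),
                 factor(cl, levels = seq_len(n_clusters)))
    counts <- matrix(as.numeric(tab), n_steps, n_clusters)
  }

  half <- ceiling(4 * sigma / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  edge <- as.numeric(stats::convolve(rep(1, n_steps), kern, type = "open"))
  edge <- edge[(half + 1):(half + n_steps)]
  dens <- matrix(0, n_steps, n_clusters)
  for (k in seq_len(n_clusters)) {
    full <- as.numeric(stats::convolve(counts[, k], kern, type = "open"))
    dens[, k] <- full[(half + 1):(half + n_steps)] / edge
  }
  dens <- dens / neurons_per_cluster

  label <- max.col(dens, ties.method = "first")
  rowmax <- dens[cbind(seq_len(n_steps), label)]
  ties <- which(rowSums(abs(dens - rowmax) < 1e-15) > 1)
  if (length(ties)) {
    for (t in ties) {
      prev <- if (t > 1) label[t - 1] else label[t]
      if (abs(dens[t, prev] - rowmax[t]) < 1e-15) label[t] <- prev
    }
  }
  structure(tibble::tibble(t_ms = t_start + dt * seq_len(n_steps),
                           label = label),
            class = c("decoded_trace", "tbl_df", "tbl", "data.frame"),
            n_clusters = n_clusters, dt = dt)
}

#' Empirical cluster-activation distribution
#'
#' Fraction of time each cluster is the decoded active cluster.
#'
#' @param trace A [active_cluster_trace()] result (or tibble with `label`).
#' @param n_clusters Number of clusters.
#' @return A [bin_distribution()].
#' @export
empirical_distribution <- function(trace, n_clusters = NULL) {
  if (is.null(n_clusters)) n_clusters <- attr(trace, "n_clusters")
  q <- tabulate(trace$label, nbins = n_clusters) / nrow(trace)
  bin_distribution(q)
}

#' Kullback-Leibler divergence between two bin distributions
#'
#' `D(q || p) = sum_k q_k log(q_k / p_k)` in nats, with `0 log 0 = 0`;
#' returns `Inf` (with a warning) when `q` has mass where `p` has none.
#'
#' @param q Empirical distribution (numeric vector summing to 1).
#' @param p Target distribution.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(q, p) {
  q <- as.numeric(q); p <- as.numeric(p)
  stopifnot(length(q) == length(p))
  if (any(q > 0 & p == 0)) {
    warning("q has mass where p is zero; KL divergence is infinite")
    return(Inf)
  }
  pos <- q > 0
  sum(q[pos] * log(q[pos] / p[pos]))
}

#' L1 learning curve from weight snapshots
#'
#' For each snapshot of the plastic matrix, the decoded distribution is
#' compared with the target by the L1 distance `sum_k |q_k - p_k|`.
#'
#' @param snapshots Snapshot list from [train_model()].
#' @param target The target [bin_distribution()].
#' @return A tibble of class `learning_curve` with columns `sample`, `t_ms`,
#'   `l1_error`.
#' @export
learning_curve <- function(snapshots, target) {
  target <- bin_distribution(target)
  rows <- purrr::map(snapshots, function(s) {
    q <- decode_weights(s$blocks, n_bins = length(target))
    tibble::tibble(sample = s$sample %||% NA_integer_, t_ms = s$t,
                   l1_error = sum(abs(as.numeric(q) - as.numeric(target))))
  })
  structure(dplyr::bind_rows(rows),
            class = c("learning_curve", "tbl_df", "tbl", "data.frame"))
}

#' Rank-based comparison of error fluctuations
#'
#' Two-sided Mann-Whitney U test on the absolute values of two series of
#' error changes (as measured between consecutive snapshots).
#'
#' @param series_A,series_B Numeric vectors of error changes.
#' @return A one-row tibble with `statistic` (U), `p.value` and the group
#'   medians of the absolute changes.
#' @export
fluctuation_test <- function(series_A, series_B) {
  ht <- stats::wilcox.test(abs(series_A), abs(series_B), exact = FALSE,
                           correct = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 median_abs_A = stats::median(abs(series_A)),
                 median_abs_B = stats::median(abs(series_B)))
}

#' Cluster switching rate of a decoded trace
#'
#' Counts label changes per second after suppressing decoder chatter: runs of
#' a label shorter than `min_dwell` ms are absorbed into the preceding label
#' before counting.
#'
#' @param trace A [active_cluster_trace()] result.
#' @param min_dwell Minimum dwell time (ms) for a label run to count.
#' @return Switching rate (Hz).
#' @export
switching_rate <- function(trace, min_dwell = 5) {
  dt <- attr(trace, "dt") %||% diff(trace$t_ms[1:2])
  r <- merged_runs(trace$label, dt = dt, min_dwell = min_dwell)
  duration_s <- (nrow(trace) * dt) / 1000
  (length(r$values) - 1) / duration_s
}

#' Leaky integration of a comparison function over decoded samples
#'
#' Implements the decision read-out
#' `r_t = (1 - dt/tau_r) r_{t-1} + (dt/tau_r) f(i, x_t)`, `r_0 = 0`, with the
#' indicator `f(i, x) = +1` if `i > x` and `-1` if `i < x`. The input `i`
#' must be a half-integer so `f` is never evaluated at `i = x`.
#'
#' @param trace A [active_cluster_trace()] result: per-step sample labels.
#' @param input The comparison input i (half-integer in `[0.5, 8.5]`).
#' @param cfg [integrator_config()] (its `dt` is replaced by the trace grid).
#' @return A tibble with columns `t_ms` and `r` (integration trajectory).
#' @export
run_decision <- function(trace, input, cfg = integrator_config()) {
  check_half_integer(input)
  dt <- attr(trace, "dt") %||% cfg$dt
  f <- ifelse(input > trace$label, 1, -1)
  lam <- dt / cfg$tau_r
  r <- stats::filter(lam * f, 1 - lam, method = "recursive")
  tibble::tibble(t_ms = trace$t_ms, r = as.numeric(r))
}

check_half_integer <- function(i) {
  if (any(abs(i - floor(i) - 0.5) > 1e-9)) {
    stop("decision inputs must be half-integers (the comparison f(i, x) is ",
         "undefined at integer i = x)")
  }
  invisible(i)
}

#' Slope of the psychometric curve
#'
#' The difference of the outputs at inputs 5.5 and 3.5, divided by two, and
#' optionally normalized by the output at 8.5 (which makes slopes comparable
#' across decision durations).
#'
#' @param outputs A data frame with columns `input` and `r` (one row per
#'   input, e.g. averaged over repeats), or a named vector.
#' @param normalize Divide by `r` at input 8.5?
#' @return Slope (scalar).
#' @export
psychometric_slope <- function(outputs, normalize = FALSE) {
  if (is.data.frame(outputs)) {
    r_at <- function(i) {
      v <- outputs$r[abs(outputs$input - i) < 1e-9]
      if (!length(v)) stop("no output at input ", i)
      mean(v)
    }
  } else {
    r_at <- function(i) unname(outputs[[as.character(i)]])
  }
  slope <- (r_at(5.5) - r_at(3.5)) / 2
  if (normalize) slope <- slope / r_at(8.5)
  slope
}

#' Regression of decision output on recent stimulus history
#'
#' Ordinary least squares of the normalized decision output on the mean of
#' the last five observed samples, with the two-sided p-value for a non-zero
#' slope. Errors on a constant regressor (degenerate design).
#'
#' @param last5_means Mean of the last five samples before each probe.
#' @param outputs_01 Decision outputs, min-max normalized to `[0, 1]`.
#' @return An object of class `history_fit` wrapping the `lm` fit; supports
#'   `tidy()`, `glance()`, `autoplot()`, `coef()` and `summary()`.
#' @export
history_regression <- function(last5_means, outputs_01) {
  stopifnot(length(last5_means) == length(outputs_01))
  if (stats::var(last5_means) < 1e-12) {
    stop("degenerate regressor: the last-five-sample means are constant")
  }
  fit <- stats::lm(outputs_01 ~ last5_means)
  sm <- summary(fit)
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 p.value = sm$coefficients[2, 4],
                 span = unname(stats::coef(fit)[2]) *
                   diff(range(last5_means)),
                 data = tibble::tibble(last5_mean = last5_means,
                                       output = outputs_01)),
            class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat(sprintf("<history_fit> slope = %.4f (p = %.4g), bias span = %.2f%% of output range\n",
              x$slope, x$p.value, 100 * x$span))
  invisible(x)
}

#' @export
coef.history_fit <- function(object, ...) stats::coef(object$fit)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Settling point of a slope series after a distribution switch
#'
#' Determines when a psychometric-slope series (declining from the old
#' distribution's steeper slope toward the new, shallower one) has reached
#' its new steady state. The steady band is the mean of the last `tail_n`
#' probes plus one standard deviation; the series is lightly smoothed (a
#' centered moving average of width `smooth`) to suppress single-probe
#' excursions, and the settling sample is the first probe from which the
#' smoothed series stays at or below the band's upper edge. The criterion is
#' one-sided because probe noise regularly dips a near-settled slope below
#' the steady mean.
#'
#' @param series Data frame with columns `sample` and `slope` (post-switch
#'   probes only, in sample order).
#' @param tail_n Number of tail probes defining the steady band.
#' @param smooth Width of the centered moving average (1 = none).
#' @param band_sd Optional lower bound on the band half-width.
#' @return List with `sample` (settling sample index; the last sample if the
#'   series never settles), `band_mean` and `band_halfwidth`.
#' @export
slope_settling <- function(series, tail_n = 8, smooth = 5, band_sd = NULL) {
  stopifnot(nrow(series) > tail_n)
  sl <- series$slope
  sm <- if (smooth > 1) {
    h <- smooth %/% 2
    vapply(seq_along(sl), function(k) {
      mean(sl[max(1, k - h):min(length(sl), k + h)])
    }, numeric(1))
  } else sl
  tail_idx <- (nrow(series) - tail_n + 1):nrow(series)
  mu <- mean(sl[tail_idx])
  half <- stats::sd(sl[tail_idx])
  if (!is.null(band_sd)) half <- max(half, band_sd)
  above <- sm > mu + half
  stays <- rev(cumprod(rev(!above))) > 0
  k <- which(stays)[1]
  if (is.na(k)) k <- nrow(series)
  list(sample = series$sample[k], band_mean = mu, band_halfwidth = half)
}
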