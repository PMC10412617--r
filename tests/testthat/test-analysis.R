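test_that("decoding labels a single active cluster correctly", {
  # only cluster 3 spikes
  sp <- tibble::tibble(population = factor("sensory"),
                       neuron = rep(21:30, each = 20),
                       t_ms = rep(seq(5, 100, by = 5), times = 10))
  tr <- active_cluster_trace(sp, "sensory", n_clusters = 8,
                             neurons_per_cluster = 10, t_start = 0,
                             t_end = 100, dt = 0.1)
  expect_true(all(tr$label == 3))
  expect_equal(nrow(tr), 1000)
  expect_error(active_cluster_trace(sp[0, ], "sensory"), "no excitatory spikes")
})

test_that("decoding recovers the switch rate of a synthetic alternating generator", {
  # two clusters alternating every 125 ms for 4 s -> 8 label changes / s
  dt <- 0.1
  t_end <- 4000
  spikes <- list()
  for (k in 0:(t_end / 125 - 1)) {
    cl <- (k %% 2) + 1
    tt <- seq(k * 125 + 1, (k + 1) * 125, by = 2)  # 500 Hz cluster burst
    spikes[[k + 1]] <- tibble::tibble(
      population = factor("sensory"),
      neuron = rep((cl - 1) * 10 + 1:10, length(tt)),
      t_ms = rep(tt, each = 10))
  }
  sp <- dplyr::bind_rows(spikes)
  tr <- active_cluster_trace(sp, "sensory", n_clusters = 8,
                             neurons_per_cluster = 10, t_start = 0,
                             t_end = t_end, dt = dt)
  expect_equal(switching_rate(tr), 8, tolerance = 0.05)
  q <- empirical_distribution(tr)
  expect_equal(as.numeric(q)[1:2], c(0.5, 0.5), tolerance = 0.02)
})

test_that("the empirical distribution of a synthetic trace equals its generator frequencies", {
  labels <- rep(c(1L, 2L, 2L, 5L), each = 250)
  tr <- make_trace(labels, n_clusters = 8)
  q <- empirical_distribution(tr)
  expect_equal(as.numeric(q), c(0.25, 0.5, 0, 0, 0.25, 0, 0, 0))
})

test_that("KL divergence has its closed-form values and satisfies Gibbs' inequality", {
  p <- bin_distribution(rep(1 / 8, 8))
  expect_equal(kl_divergence(p, p), 0)
  point <- c(1, rep(0, 7))
  expect_equal(kl_divergence(point, p), log(8))
  expect_warning(kl <- kl_divergence(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0)),
                 "infinite")
  expect_equal(kl, Inf)
  set.seed(4)
  for (k in 1:50) {
    q <- as.numeric(bin_distribution(prop.table(runif(8) + 1e-3)))
    p2 <- as.numeric(bin_distribution(prop.table(runif(8) + 1e-3)))
    expect_gte(kl_divergence(q, p2), 0)
  }
})

test_that("the mean KL of finite empirical distributions matches the asymptotic bias", {
  # for n i.i.d. samples from p over 8 bins, E[KL] ~ (8 - 1) / (2n) nats
  set.seed(9)
  p <- rep(1 / 8, 8)
  n <- 2000
  reps <- 400
  kls <- replicate(reps, {
    q <- tabulate(sample.int(8, n, replace = TRUE), 8) / n
    kl_divergence(q, p)
  })
  expected <- 7 / (2 * n)
  expect_equal(mean(kls), expected, tolerance = 0.1)
})

test_that("learning curves hit zero on exact encodings and ignore global scale", {
  p <- target_distribution("uniform")
  W <- init_plastic_weights(p, C = 8, n_pre_per_cluster = 5,
                            n_post_per_cluster = 5)
  snaps <- list(list(t = 1000, blocks = block_sums(W, 8, 8), sample = 5),
                list(t = 2000, blocks = block_sums(W * 2, 8, 8), sample = 10))
  lc <- learning_curve(snaps, p)
  expect_equal(lc$l1_error, c(0, 0))
  expect_equal(lc$sample, c(5, 10))
})

test_that("the rank-sum statistic equals brute-force pair counting on a toy input", {
  a <- c(0.1, -0.4, 0.2)
  b <- c(0.5, -0.6, 0.05)
  res <- fluctuation_test(a, b)
  # brute force: count pairs where |a_i| > |b_j| (no ties here)
  U <- sum(outer(abs(a), abs(b), ">"))
  expect_equal(unname(res$statistic), U)
  same <- fluctuation_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p.value, 0.9)
})

test_that("switching rates handle constant, periodic, and chattering traces", {
  expect_equal(switching_rate(make_trace(rep(2L, 1000))), 0)
  labels <- rep(rep(1:2, 10), each = 500)  # alternate every 50 ms for 1 s
  expect_equal(switching_rate(make_trace(labels)), 19)  # 19 changes in 1 s
  # a 2 ms blip is absorbed by the 5 ms dwell filter
  blip <- c(rep(1L, 600), rep(2L, 20), rep(1L, 380))
  expect_equal(switching_rate(make_trace(blip)), 0)
  expect_equal(switching_rate(make_trace(blip), min_dwell = 0), 20)
})

test_that("the decision integrator follows its closed form and is linear in f", {
  cfg <- integrator_config(tau_r = 1000, dt = 0.1)
  labels <- rep(1L, 20000)  # 2 s, all samples below i = 8.5 -> f = +1
  tr <- make_trace(labels, n_clusters = 8)
  out <- run_decision(tr, 8.5, cfg)
  n <- nrow(out)
  lam <- 0.1 / 1000
  expect_equal(out$r[n], 1 - (1 - lam)^n, tolerance = 1e-12)
  expect_equal(out$r[n], 1 - exp(-2), tolerance = 1e-3)
  # f = -1 throughout gives the exact negation
  out_neg <- run_decision(tr, 0.5, cfg)
  expect_equal(out_neg$r, -out$r)
  # integer inputs are rejected: f(i, x) is undefined at i = x
  expect_error(run_decision(tr, 4), "half-integer")
})

test_that("psychometric slopes match the CDF closed form for an ideal sampler", {
  p <- target_distribution("uniform")
  r_ideal <- stats::setNames(
    as.list(2 * bin_cdf(p, c(3.5, 5.5, 8.5)) - 1), c(3.5, 5.5, 8.5))
  expect_equal(psychometric_slope(r_ideal), 0.25)
  df <- tibble::tibble(input = c(3.5, 5.5, 8.5),
                       r = 2 * bin_cdf(p, c(3.5, 5.5, 8.5)) - 1)
  expect_equal(psychometric_slope(df), 0.25)
  expect_equal(psychometric_slope(df, normalize = TRUE), 0.25)  # r(8.5) = 1
})

test_that("history regression reproduces closed-form least squares and flags degeneracy", {
  x <- c(2, 3, 4, 5, 6)
  y <- c(0.1, 0.3, 0.35, 0.6, 0.8)
  fit <- history_regression(x, y)
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, beta_hat, tolerance = 1e-12)
  expect_equal(fit$span, beta_hat * 4, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(unname(td$estimate[2]), beta_hat)
  gl <- glance(fit)
  expect_equal(gl$nobs, 5)
  expect_error(history_regression(rep(4, 5), y), "degenerate")
  # shuffled outputs: slope indistinguishable from zero
  set.seed(21)
  xs <- runif(200); ys <- sample(runif(200))
  expect_gt(history_regression(xs, ys)$p.value, 0.01)
})
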