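test_that("training rejects invalid streams and handles the empty stream", {
  m <- tiny_model(C = 3, npc = 8, seed = 5)
  expect_error(train_model(m, c(1L, 9L), seed = 1), "1..8")
  expect_error(train_model(m, 0L, seed = 1), "1..8")
  tr <- train_model(m, integer(0), seed = 1)
  expect_identical(unclass(tr$model$W_plastic)[, ], unclass(m$W_plastic)[, ])
  expect_equal(nrow(tr$spikes), 0)
})

test_that("training snapshots arrive every fifth presentation with sample indices", {
  m <- tiny_model(C = 3, npc = 8, seed = 5)
  tr <- train_model(m, rep(c(2L, 6L), 6), seed = 3)  # 12 samples
  expect_length(tr$snapshots, 2)
  expect_equal(vapply(tr$snapshots, `[[`, numeric(1), "sample"), c(5, 10))
  expect_equal(vapply(tr$snapshots, `[[`, numeric(1), "t"), c(1000, 2000))
  # blocks have one row per uniform cluster and one column per sensory cluster
  expect_equal(dim(tr$snapshots[[1]]$blocks), c(3, 8))
})

test_that("repeated observations of one bin repoint uniform clusters to it", {
  set.seed(42)
  m <- tiny_model(C = 4, npc = 15, seed = 7)
  warm <- simulate_spontaneous(m, 400, seed = 2, plasticity = FALSE)
  q0 <- as.numeric(decode_weights(warm$model$W_plastic))
  tr <- train_model(warm$model, rep(7L, 8), seed = 3)
  q1 <- as.numeric(decode_weights(tr$model$W_plastic))
  # the observed bin gains stored probability (partial repointing is expected
  # at miniature scale, where eligibility of the active cluster is sparse)
  expect_gt(q1[7], q0[7] + 0.03)
})

test_that("decision probes return one output per input and advance the model clock", {
  m <- tiny_model(C = 3, npc = 10, seed = 6)
  pr <- decision_probe(m, c(2.5, 4.5, 8.5), duration = 400, seed = 4)
  expect_named(pr$r, c("2.5", "4.5", "8.5"))
  expect_true(all(abs(pr$r) <= 1))
  expect_equal(pr$model$t0, 400)
  expect_error(decision_probe(m, 3, duration = 200, seed = 1), "half-integer")
})

test_that("psychometric curves aggregate repeats with mean and SD", {
  m <- tiny_model(C = 3, npc = 10, seed = 6)
  pc <- psychometric_experiment(m, inputs = c(0.5, 4.5, 8.5), duration = 300,
                                repeats = 2, seed = 5, share_traces = TRUE)
  expect_s3_class(pc, "psychometric_curve")
  expect_equal(pc$input, c(0.5, 4.5, 8.5))
  expect_equal(pc$n, rep(2, 3))
  # the extreme inputs bound every trajectory: r(0.5) <= r(8.5) always
  expect_true(all(pc$r_mean[1] <= pc$r_mean[3]))
  probes <- attr(pc, "probes")
  expect_equal(nrow(probes), 6)
})

test_that("the mean psychometric output of ideal sampler streams is 2F(i) - 1", {
  # independent label streams from the stored distribution (the cluster-level
  # picture of spontaneous sampling), integrated by the decision read-out
  set.seed(31)
  p <- target_distribution("biased")
  st <- oracle_state(24, p)
  inputs <- seq(0.5, 8.5, by = 1)
  cfg <- integrator_config(tau_r = 1000, dt = 1)
  r_bar <- rep(0, 9)
  reps <- 60
  for (k in seq_len(reps)) {
    labels <- rep(oracle_sample_stream(st, 64), each = 125)  # 8 Hz, 8 s
    tr <- make_trace(labels, dt = 1, n_clusters = 8)
    r_bar <- r_bar + vapply(inputs, function(i) {
      out <- run_decision(tr, i, cfg)
      out$r[nrow(out)]
    }, numeric(1))
  }
  r_bar <- r_bar / reps
  expected <- (2 * bin_cdf(oracle_distribution(st), inputs) - 1) *
    (1 - exp(-8))  # integrator attenuation at 8 s
  expect_equal(r_bar, expected, tolerance = 0.12)
  # monotone non-decreasing in i up to sampling noise
  expect_true(all(diff(r_bar) > -0.05))
})

test_that("history experiments pair probes with the last five samples", {
  m <- tiny_model(C = 3, npc = 8, seed = 8)
  h <- history_experiment(m, target_distribution("uniform"), n_samples = 10,
                          probe_every = 5, probe_duration = 300, seed = 9,
                          encode = FALSE)
  expect_equal(nrow(h), 2)
  expect_equal(h$after_sample, c(5, 10))
  expect_true(all(h$last5_mean >= 1 & h$last5_mean <= 8))
  # min-max normalization puts the outputs in [0, 1]
  expect_true(all(h$r01 >= 0 & h$r01 <= 1, na.rm = TRUE))
})

test_that("recall experiments need a read-out network and report per-cluster rates", {
  m <- tiny_model(C = 3, npc = 8, seed = 5)
  expect_error(recall_experiment(m, duration = 100, seed = 1), "readout")
  mr <- tiny_model(C = 3, npc = 8, seed = 5, readout = TRUE)
  rc <- recall_experiment(mr, duration = 2500, seed = 2, discard = 500,
                          min_dwell = 10)
  expect_s3_class(rc, "recall_result")
  expect_equal(nrow(rc), 8)
  expect_true(all(rc$rate_hz >= 0, na.rm = TRUE))
  expect_equal(sum(rc$probability), 1, tolerance = 1e-9)
})

test_that("experiment drivers are reproducible under a fixed seed", {
  m <- tiny_model(C = 3, npc = 8, seed = 5)
  h1 <- history_experiment(m, target_distribution("uniform"), n_samples = 5,
                           probe_duration = 200, seed = 4, encode = FALSE)
  h2 <- history_experiment(m, target_distribution("uniform"), n_samples = 5,
                           probe_duration = 200, seed = 4, encode = FALSE)
  expect_identical(h1$r_raw, h2$r_raw)
})
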