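test_that("eligibility marks neurons that fired within the window", {
  expect_equal(eligibility(c(-10, -20, -Inf), t = 0, window = 15), c(1, 0, 0))
  expect_equal(eligibility(0, t = 0), 1)  # a spike right now counts
  expect_error(eligibility(5, t = 0), "future")
})

test_that("the eligibility fraction of Poisson trains matches 1 - exp(-rate * window)", {
  set.seed(7)
  rate <- 0.04  # kHz -> 40 Hz
  window <- 15
  n <- 20000
  # last spike of a stationary Poisson train: Exp(rate) backwards in time
  last <- -stats::rexp(n, rate)
  frac <- mean(eligibility(last, t = 0, window = window))
  expected <- 1 - exp(-rate * window)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("the Hebbian/normalization step is a no-op at its fixed point and when frozen", {
  pp <- plasticity_params(K_norm = 20)
  W <- matrix(c(5, 5, 5, 5, 0, 0, 0, 0), nrow = 4, ncol = 2)  # colsums 20, 0
  W0 <- W
  # col 1 at the fixed point, no eligibility: unchanged
  W1 <- hebb_norm_step(W, y_post = rep(0, 4), y_pre = c(0, 0), pp, dt = 0.1)
  expect_equal(W1[, 1], W0[, 1])
  expect_gt(sum(W1[, 2]), 0)  # col 2 is below K and gets pulled up
  # frozen mode: bitwise no-op regardless of eligibility
  ppf <- plasticity_params(K_norm = 20, enabled = FALSE)
  expect_identical(hebb_norm_step(W, rep(1, 4), c(1, 1), ppf, dt = 0.1), W)
})

test_that("a 50 ms pairing matches a fine-step Euler reference of the weight ODE", {
  n_post <- 60; n_pre <- 3
  pp <- plasticity_params(K_norm = 100, A_p = 0.5, tau_n = 100,
                          W_min = 0, W_max = 5)
  set.seed(3)
  W0 <- matrix(runif(n_post * n_pre, 0, 3), n_post, n_pre)
  y_post <- as.numeric(seq_len(n_post) <= 20)  # one coactive cluster
  y_pre <- c(1, 0, 0)

  evolve <- function(W, dt, t_total) {
    for (k in seq_len(round(t_total / dt))) {
      W <- hebb_norm_step(W, y_post, y_pre, pp, dt)
    }
    W
  }
  W_coarse <- evolve(W0, 0.1, 50)
  W_fine <- evolve(W0, 0.002, 50)
  expect_equal(W_coarse, W_fine, tolerance = 5e-3)
  # the coactive block potentiates, the rest of that column pays for it
  expect_gt(mean(W_coarse[1:20, 1] - W0[1:20, 1]), 0)
})

test_that("each presynaptic outgoing sum converges to K against the scalar closed form", {
  # the same scalar deficit drives every outgoing weight, so with n interior
  # entries (clipping inactive) the sum relaxes to K at rate n / tau_n
  pp <- plasticity_params(K_norm = 50, tau_n = 100, W_min = 0, W_max = 5)
  n_post <- 25
  W <- matrix(1, n_post, 1)  # sum 25, deficit 25
  S0 <- sum(W)
  times <- c(2, 4, 8)
  dt <- 0.1
  W_t <- W
  t_done <- 0
  for (tt in times) {
    for (k in seq_len(round((tt - t_done) / dt))) {
      W_t <- hebb_norm_step(W_t, rep(0, n_post), 0, pp, dt)
    }
    t_done <- tt
    S_expected <- pp$K_norm + (S0 - pp$K_norm) * exp(-n_post * tt / pp$tau_n)
    expect_equal(sum(W_t), S_expected, tolerance = 1e-2)
  }
  # the normalization move never overshoots K, even with a coarse step
  W_big <- matrix(4, n_post, 1)  # sum 100, surplus 50
  W_next <- hebb_norm_step(W_big, rep(0, n_post), 0, pp, dt = 50)
  expect_gte(sum(W_next), pp$K_norm)
})

test_that("probability is conserved: potentiation of one block depresses the previous one", {
  # one presynaptic column fully assigned to block A, then paired with block B
  n_post <- 40  # two blocks of 20
  pp <- plasticity_params(K_norm = 20 * 5, A_p = 0.5, tau_n = 100)
  W <- matrix(0, n_post, 1); W[1:20, 1] <- 5  # block A at the cap, sum = K
  y_pre <- 1
  y_post <- c(rep(0, 20), rep(1, 20))  # block B active with the presyn neuron
  for (k in seq_len(500)) W <- hebb_norm_step(W, y_post, y_pre, pp, dt = 0.1)
  gain_B <- sum(W[21:40, 1])
  loss_A <- 100 - sum(W[1:20, 1])
  expect_gt(gain_B, 0)
  expect_gt(loss_A, 0)
  # once the pairing ends, normalization works off the transient excess and
  # the gained probability equals the lost probability
  for (k in seq_len(round(1500 / 0.1))) {
    W <- hebb_norm_step(W, rep(0, n_post), 0, pp, dt = 0.1)
  }
  expect_equal(sum(W), pp$K_norm, tolerance = 1e-3)
  expect_equal(sum(W[21:40, 1]), 100 - sum(W[1:20, 1]), tolerance = 1e-3)
})

test_that("frozen plasticity leaves weights bitwise unchanged through a full simulation", {
  m <- tiny_model(C = 3, npc = 8, seed = 5)
  W0 <- unclass(m$W_plastic)
  tr <- train_model(m, c(1L, 5L, 3L), seed = 9, plasticity_enabled = FALSE)
  expect_identical(unclass(tr$model$W_plastic)[, ], W0[, ])
  sp <- simulate_spontaneous(tr$model, 300, seed = 10, plasticity = FALSE)
  expect_identical(unclass(sp$model$W_plastic)[, ], W0[, ])
})

test_that("short-term plasticity follows the printed per-spike rule", {
  ps <- stp_params()
  # one spike from baseline: 0.95 x 4 = 3.8 pF (recovery over one dt is tiny)
  w <- stp_step(4, TRUE, ps, dt = 0)
  expect_equal(w, 3.8)
  # facilitation caps at 6 pF
  pf <- stp_params(mode = "facilitation")
  w <- 5.9
  for (k in 1:10) w <- stp_step(w, TRUE, pf, dt = 0)
  expect_equal(w, 6)
  # depressed weights recover exponentially toward baseline with tau = 2 s
  w <- 2; dt <- 0.5
  for (k in seq_len(round(2000 / dt))) w <- stp_step(w, FALSE, ps, dt)
  expect_equal(w, 4 - 2 * exp(-1), tolerance = 1e-3)
  # disabled: no change
  expect_equal(stp_step(3, TRUE, stp_params(enabled = FALSE), 0.1), 3)
})

test_that("the STP steady state under Poisson spiking matches the fixed-point analysis", {
  # mean-field fixed point of dw/dt = (b - w)/tau - f nu w: w* = b / (1 + f nu tau)
  ps <- stp_params()
  nu <- 0.02  # kHz = 20 Hz
  dt <- 0.1
  set.seed(11)
  n_steps <- 4e5
  w <- 4; acc <- 0; n_acc <- 0
  spikes <- stats::rpois(n_steps, nu * dt) > 0
  for (k in seq_len(n_steps)) {
    w <- stp_step(w, spikes[k], ps, dt)
    if (k > n_steps / 4) { acc <- acc + w; n_acc <- n_acc + 1 }
  }
  w_star <- ps$baseline / (1 + ps$step_fraction * nu * ps$recovery_tau)
  expect_equal(acc / n_acc, w_star, tolerance = 0.05)
})

test_that("decode_weights returns the stored distribution in both matrix forms", {
  p <- target_distribution("biased")
  W <- init_plastic_weights(p, C = 6, n_pre_per_cluster = 4,
                            n_post_per_cluster = 4)
  counts <- tabulate(attr(W, "assignment"), 8)
  expect_equal(as.numeric(decode_weights(W)), counts / 6)
  # block-sum form (C x n_bins) gives the same answer
  b <- block_sums(W, n_bins = 8, C = 6)
  expect_equal(as.numeric(decode_weights(b)), counts / 6)
  # invariant to global rescaling
  expect_equal(as.numeric(decode_weights(W * 3.7)), counts / 6)
  expect_error(decode_weights(matrix(0, 8, 4)), "all-zero")
  # always a valid distribution for admissible inputs
  set.seed(2)
  Wr <- matrix(runif(16 * 6), 16, 6)
  q <- decode_weights(Wr, n_bins = 8)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_true(all(q >= 0))
})
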