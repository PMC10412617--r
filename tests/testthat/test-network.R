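test_that("population sizes follow the architecture rules", {
  u <- build_uniform_sampler(C = 24, neurons_per_cluster = 100, seed = 1)
  expect_equal(u$n_E, 2400)
  expect_equal(u$n_I, 600)   # 25 inhibitory neurons per cluster
  s <- build_sensory(neurons_per_cluster = 100, seed = 1)
  expect_equal(s$n_E, 800)
  expect_equal(s$n_I, 200)
  r <- build_readout(neurons_per_cluster = 100, seed = 1)
  expect_equal(r$n_E, 800)
  expect_equal(r$n_I, 200)
  expect_equal(r$n_clusters, 1)
})

test_that("weights follow the printed scaling rules", {
  s <- build_sensory(neurons_per_cluster = 100, seed = 3)
  eidx <- seq_len(s$n_E)
  Wee <- s$W[eidx, eidx]
  between <- Wee[outer(s$cluster_id, s$cluster_id, "!=") & Wee > 0]
  within <- Wee[outer(s$cluster_id, s$cluster_id, "==") & Wee > 0]
  expect_true(all(between == 5))       # baseline E-to-E, f = 1
  expect_true(all(within == 50))       # 10 x 5 pF within a cluster
  iidx <- s$n_E + seq_len(s$n_I)
  expect_true(all(s$W[eidx, iidx][s$W[eidx, iidx] > 0] == 175))
  expect_true(all(s$W[iidx, iidx][s$W[iidx, iidx] > 0] == 35))
  expect_true(all(s$W[iidx, eidx][s$W[iidx, eidx] > 0] == 5))

  # uniform sampler at C clusters: baseline x sqrt(8/C), within x 10 sqrt(C/6)
  for (C in c(8, 24)) {
    u <- build_uniform_sampler(C = C, neurons_per_cluster = 100, seed = 2)
    f <- sqrt(8 / C)
    eidx <- seq_len(u$n_E)
    Wee <- u$W[eidx, eidx]
    between <- Wee[outer(u$cluster_id, u$cluster_id, "!=") & Wee > 0]
    within <- Wee[outer(u$cluster_id, u$cluster_id, "==") & Wee > 0]
    expect_equal(unique(between), 5 * f, tolerance = 1e-12)
    expect_equal(unique(within), 5 * f * 10 * sqrt(C / 6), tolerance = 1e-12)
  }
})

test_that("no self-connections and reproducible draws", {
  u <- build_uniform_sampler(C = 4, neurons_per_cluster = 20, seed = 7)
  expect_true(all(diag(u$W) == 0))
  u2 <- build_uniform_sampler(C = 4, neurons_per_cluster = 20, seed = 7)
  expect_identical(u$W, u2$W)
  u3 <- build_uniform_sampler(C = 4, neurons_per_cluster = 20, seed = 8)
  expect_false(identical(u$W, u3$W))
})

test_that("the realized connection count sits inside the exact binomial band", {
  u <- build_uniform_sampler(C = 6, neurons_per_cluster = 50, seed = 11)
  n <- u$n_E + u$n_I
  k <- sum(u$W > 0)
  trials <- n * (n - 1)
  band <- qbinom(c(0.005, 0.995), trials, 0.2)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("initial plastic weights encode the target with largest-remainder counts", {
  p <- target_distribution("uniform")
  W <- init_plastic_weights(p, C = 24, n_pre_per_cluster = 10,
                            n_post_per_cluster = 10)
  expect_equal(tabulate(attr(W, "assignment"), 8), rep(3L, 8))
  # each presynaptic neuron's outgoing sum equals K = cluster size x W_max
  expect_equal(unique(colSums(W)), 10 * 5)
  # full-size consistency with the canonical normalization constant
  Wf <- init_plastic_weights(p, C = 24)
  expect_equal(unique(colSums(Wf)), 500)

  # decode is the exact inverse for distributions representable over C
  for (shape in c("uniform", "biased", "unimodal", "bimodal")) {
    pt <- target_distribution(shape)
    q_round <- spikesampler:::largest_remainder(as.numeric(pt) * 24) / 24
    W <- init_plastic_weights(pt, C = 24, n_pre_per_cluster = 5,
                              n_post_per_cluster = 5)
    expect_equal(as.numeric(decode_weights(W)), q_round, tolerance = 1e-12)
  }
})

test_that("largest-remainder apportionment is exact and breaks ties low", {
  lr <- spikesampler:::largest_remainder
  expect_equal(lr(c(1.5, 1.5, 1)), c(2L, 1L, 1L))  # tie goes to the lower index
  expect_equal(sum(lr(runif(8) * 0 + 3)), 24)
  x <- c(2.6, 2.6, 2.8) * 5 / sum(c(2.6, 2.6, 2.8)) * 3  # sums to ~ non-integer parts
  expect_equal(sum(lr(c(0.3, 0.3, 0.4) * 10)), 10)
})

test_that("reduced cluster sizes apply the square-root weight compensation", {
  s_full <- build_sensory(neurons_per_cluster = 100, seed = 5)
  s_half <- build_sensory(neurons_per_cluster = 25, seed = 5)
  w_full <- unique(s_full$W[s_full$W > 0])
  w_half <- unique(s_half$W[s_half$W > 0])
  expect_equal(sort(w_half), sort(w_full) * 2, tolerance = 1e-12)
})
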