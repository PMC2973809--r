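test_that("mean trajectories evaluate the harmonic form and are periodic", {
  m0 <- continuous_cycle_model(
    baseline = c(10, 12), amplitude = c(0, 0), phase = c(1, 2),
    noise_sd = c(1, 1)
  )
  for (t in c(0, 0.3, 0.77)) {
    expect_equal(unname(eval_mean_trajectory(m0, t)), c(10, 12))
  }

  m1 <- continuous_cycle_model(10, 5, 0, 1)
  expect_equal(unname(eval_mean_trajectory(m1, 0)), 15)
  expect_equal(unname(eval_mean_trajectory(m1, 0.5)), 5)

  m2 <- sample_cycle_params(5, seed = 7)
  tt <- c(0.11, 0.42, 0.9)
  expect_equal(eval_mean_trajectory(m2, tt),
               eval_mean_trajectory(m2, tt + m2$period),
               tolerance = 1e-12)
})

test_that("burst probabilities follow the clipped harmonic expansion", {
  flat <- burst_cycle_model(mean_prob = c(0.2, 0.7), amplitude = c(0, 0),
                            phase = c(0, 1))
  expect_equal(unname(eval_burst_prob(flat, 0.3)), c(0.2, 0.7))

  locked <- burst_cycle_model(mean_prob = 0.3, phase = 0,
                              amplitude_locked = TRUE)
  expect_equal(unname(eval_burst_prob(locked, 0.5)), 0)  # cos = -1
  expect_equal(unname(eval_burst_prob(locked, 0)), 0.6)

  clip <- burst_cycle_model(mean_prob = 0.9, amplitude = 0.3, phase = 0)
  expect_equal(unname(eval_burst_prob(clip, 0)), 1)

  # global factor scales before clipping
  expect_equal(unname(eval_burst_prob(flat, 0, global_factor = 2)),
               c(0.4, 1))
})

test_that("model constructors enforce their invariants", {
  expect_error(continuous_cycle_model(5, 6, 0, 1), "amplitude")
  expect_error(continuous_cycle_model(5, 2, 0, 0), "noise_sd")
  expect_error(burst_cycle_model(1.2, amplitude = 0.1, phase = 0), "mean_prob")
  expect_error(switch_model(c(0.6, 0.6), cbind(0.5, 0.5)), "sum to 1")
  expect_error(switch_model(c(0.5, 0.5), cbind(1.4, 0.2)), "burst_prob")
  expect_error(
    burst_cycle_model(0.3, phase = cbind(0, 1), amplitude_locked = TRUE),
    "one harmonic"
  )
})

test_that("closed-form moments match hand-computable cases", {
  m <- burst_cycle_model(mean_prob = c(0.3, 0.4), amplitude = c(0.2, 0.2),
                         phase = c(0, pi / 2))
  expect_equal(exact_moments(m)$cov[1, 2], 0, tolerance = 1e-14)

  sw <- switch_model(c(0.5, 0.5), cbind(c(1, 1), c(0, 0)))
  expect_equal(exact_moments(sw)$cov[1, 2], 0.25)

  # generic two-gene closed form: 0.5 a_i a_j cos(dphi)
  m2 <- burst_cycle_model(mean_prob = c(0.2, 0.3),
                          amplitude = c(0.15, 0.1), phase = c(0.4, 1.9))
  expect_equal(exact_moments(m2)$cov[1, 2],
               0.5 * 0.15 * 0.1 * cos(0.4 - 1.9))
})

test_that("quadrature moments agree with closed form when clipping is inactive", {
  for (s in 1:5) {
    m <- sample_burst_cycle_params(4, seed = s)
    cf <- exact_moments(m)
    qd <- exact_moments(m, method = "quadrature")
    expect_equal(qd$mean, cf$mean, tolerance = 1e-10)
    expect_lt(max(abs(qd$cov - cf$cov)), 1e-9)
  }
})

test_that("closed-form moments match a Monte-Carlo time-sampling oracle", {
  m <- sample_burst_cycle_params(2, seed = 42)
  tt <- with_seed_local(99, runif(1e6))
  p1 <- m$mean_prob[1] + m$amplitude[1, 1] * cos(2 * pi * tt + m$phase[1, 1])
  p2 <- m$mean_prob[2] + m$amplitude[2, 1] * cos(2 * pi * tt + m$phase[2, 1])
  mc <- block_cov_se(p1, p2)
  expect_within_3se(mc$mean, mc$se, exact_moments(m)$cov[1, 2])
})

test_that("global noise enters moments as derived and vanishes at sigma_G = 0", {
  base <- sample_burst_cycle_params(3, seed = 8)
  noisy <- burst_cycle_model(
    mean_prob = base$mean_prob, amplitude = base$amplitude,
    phase = base$phase, global_noise_sd = 0.5
  )
  m0 <- exact_moments(base)$cov
  m1 <- exact_moments(noisy)$cov
  expected <- 0.25 * tcrossprod(base$mean_prob) + 1.25 * m0
  expect_equal(unname(m1), unname(expected), tolerance = 1e-12)

  zero <- burst_cycle_model(
    mean_prob = base$mean_prob, amplitude = base$amplitude,
    phase = base$phase, global_noise_sd = 0
  )
  expect_equal(exact_moments(zero)$cov, m0)
})

test_that("moments are invariant under global phase shift and reflection", {
  m <- sample_burst_cycle_params(4, seed = 13, global_noise_sd = 0.3)
  shifted <- burst_cycle_model(
    mean_prob = m$mean_prob, amplitude = m$amplitude,
    phase = m$phase + 1.234, global_noise_sd = m$global_noise_sd
  )
  reflected <- burst_cycle_model(
    mean_prob = m$mean_prob, amplitude = m$amplitude,
    phase = -m$phase, global_noise_sd = m$global_noise_sd
  )
  expect_equal(exact_moments(shifted)$cov, exact_moments(m)$cov,
               tolerance = 1e-12)
  expect_equal(exact_moments(reflected)$cov, exact_moments(m)$cov,
               tolerance = 1e-12)
})

test_that("covariance ranks follow the family rank laws", {
  expect_equal(covariance_rank(matrix(0, 4, 4)), 0L)
  expect_error(covariance_rank(matrix(1:9, 3, 3)), "symmetric")

  for (s in 1:20) {
    m1 <- sample_burst_cycle_params(5, seed = 100 + s)
    expect_equal(covariance_rank(exact_moments(m1)$cov), 2L)

    mg <- burst_cycle_model(
      mean_prob = m1$mean_prob, amplitude = m1$amplitude,
      phase = m1$phase, global_noise_sd = 0.4
    )
    expect_equal(covariance_rank(exact_moments(mg)$cov), 3L)

    sw2 <- sample_switch_params(5, n_states = 2, seed = 200 + s)
    expect_equal(covariance_rank(exact_moments(sw2)$cov), 1L)

    sw3 <- sample_switch_params(6, n_states = 3, seed = 300 + s)
    expect_equal(covariance_rank(exact_moments(sw3)$cov), 2L)
  }

  # two harmonics: rank 4
  set.seed(9)
  m2 <- burst_cycle_model(
    mean_prob = runif(6, 0.3, 0.5),
    amplitude = matrix(runif(12, 0.02, 0.08), 6, 2),
    phase = matrix(runif(12, 0, 2 * pi), 6, 2)
  )
  expect_equal(covariance_rank(exact_moments(m2)$cov), 4L)
})
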