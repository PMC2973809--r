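test_that("parameter draws are deterministic given a seed and satisfy positivity", {
  m1 <- sample_cycle_params(6, seed = 3)
  m2 <- sample_cycle_params(6, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(m1$amplitude <= m1$baseline))
  expect_true(all(m1$noise_sd > 0))

  d1 <- simulate_bursty(sample_burst_cycle_params(3, seed = 1),
                        n_obs_per_pair = 50, seed = 5)
  d2 <- simulate_bursty(sample_burst_cycle_params(3, seed = 1),
                        n_obs_per_pair = 50, seed = 5)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("drawn phases are uniform on the circle", {
  phases <- with_seed_local(11, {
    vapply(1:2500, function(i) sample_cycle_params(4)$phase[1], numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(phases / (2 * pi), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous observations sit on the trajectory curve at tiny noise", {
  m <- continuous_cycle_model(
    baseline = c(10, 14), amplitude = c(5, 6), phase = c(0.3, 2.1),
    noise_sd = c(1e-9, 1e-9)
  )
  d <- simulate_continuous(m, n_obs_per_pair = 50, seed = 4)
  tt <- seq(0, 1, length.out = 20001)
  mu <- eval_mean_trajectory(m, tt)
  dist <- vapply(seq_len(nrow(d)), function(r) {
    min(sqrt((d$count_a[r] - mu[1, ])^2 + (d$count_b[r] - mu[2, ])^2))
  }, numeric(1))
  expect_lt(max(dist), 1e-2)  # bounded by curve discretization
})

test_that("continuous sample means converge to the baseline", {
  m <- continuous_cycle_model(
    baseline = c(20, 25), amplitude = c(5, 6), phase = c(0, 1),
    noise_sd = c(2, 2)
  )  # trough far above zero: floor inactive
  d <- simulate_continuous(m, n_obs_per_pair = 1e5, seed = 6)
  st <- block_se(d$count_a)
  expect_within_3se(st$mean, st$se, 20)

  # in-phase equal-amplitude pair correlates positively
  m2 <- continuous_cycle_model(
    baseline = c(20, 20), amplitude = c(6, 6), phase = c(1, 1),
    noise_sd = c(1, 1)
  )
  d2 <- simulate_continuous(m2, n_obs_per_pair = 2000, seed = 7)
  expect_gt(cor(d2$count_a, d2$count_b), 0.5)
})

test_that("bursty simulation reproduces independence and exact moments", {
  flat <- burst_cycle_model(mean_prob = c(0.5, 0.5), amplitude = c(0, 0),
                            phase = c(0, 0))
  d <- simulate_bursty(flat, n_obs_per_pair = 4e4, seed = 8)
  co <- block_se(d$count_a * d$count_b)
  expect_within_3se(co$mean, co$se, 0.25)

  m <- sample_burst_cycle_params(2, seed = 21)
  d2 <- simulate_bursty(m, n_obs_per_pair = 1e5, seed = 9)
  p1 <- block_se(d2$count_a)
  expect_within_3se(p1$mean, p1$se, m$mean_prob[1])
  cc <- block_cov_se(d2$count_a, d2$count_b)
  expect_within_3se(cc$mean, cc$se, exact_moments(m)$cov[1, 2])
})

test_that("bursty counts mode dresses indicators with geometric burst sizes", {
  m <- sample_burst_cycle_params(2, seed = 31)
  d <- simulate_bursty(m, n_obs_per_pair = 5000, seed = 10,
                       output = "counts", burst_size_mean = 8)
  expect_true(all(d$count_a == floor(d$count_a)))
  pos <- d$count_a[d$count_a > 0]
  expect_gt(length(pos), 100)
  expect_equal(mean(pos), 8, tolerance = 0.15)
})

test_that("switch simulation matches exact moments", {
  same <- switch_model(c(0.5, 0.5), cbind(c(0.4, 0.6), c(0.4, 0.6)))
  d <- simulate_switch(same, n_obs_per_pair = 4e4, seed = 11)
  cc <- block_cov_se(d$count_a, d$count_b)
  expect_within_3se(cc$mean, cc$se, 0)

  anti <- switch_model(c(0.5, 0.5), cbind(c(1, 1), c(0, 0)))
  d2 <- simulate_switch(anti, n_obs_per_pair = 4e4, seed = 12)
  cc2 <- block_cov_se(d2$count_a, d2$count_b)
  expect_within_3se(cc2$mean, cc2$se, 0.25)

  sw3 <- sample_switch_params(2, n_states = 3, seed = 41)
  d3 <- simulate_switch(sw3, n_obs_per_pair = 1e5, seed = 13)
  ex <- exact_moments(sw3)
  p1 <- block_se(d3$count_a)
  expect_within_3se(p1$mean, p1$se, ex$mean[1])
  cc3 <- block_cov_se(d3$count_a, d3$count_b)
  expect_within_3se(cc3$mean, cc3$se, ex$cov[1, 2])
})

test_that("the informative-gene constraint enforces state separation", {
  sw <- sample_switch_params(8, min_separation = 0.3, seed = 51)
  expect_true(all(abs(sw$burst_prob[, 1] - sw$burst_prob[, 2]) >= 0.3))
})

test_that("global noise shared within a cell creates positive extra covariance", {
  m <- burst_cycle_model(mean_prob = c(0.3, 0.3), amplitude = c(0, 0),
                         phase = c(0, 0), global_noise_sd = 0.5)
  d <- simulate_bursty(m, n_obs_per_pair = 1e5, seed = 14)
  cc <- block_cov_se(d$count_a, d$count_b)
  # flat probabilities: all covariance comes from the shared global factor
  expect_within_3se(cc$mean, cc$se, exact_moments(m, method = "quadrature")$cov[1, 2])
  expect_gt(cc$mean, 0.01)
})
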