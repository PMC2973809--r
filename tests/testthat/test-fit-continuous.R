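test_that("pair likelihood reduces to independent Gaussians for flat trajectories", {
  m <- continuous_cycle_model(
    baseline = c(10, 12), amplitude = c(0, 0), phase = c(0.5, 1),
    noise_sd = c(2, 3)
  )
  x <- c(9, 11, 15)
  y <- c(13, 12, 8)
  ll <- pair_loglik(m, c(1, 2), x, y)
  expect_equal(ll, dnorm(x, 10, 2, log = TRUE) + dnorm(y, 12, 3, log = TRUE))
})

test_that("pair likelihood is symmetric and converges in quadrature order", {
  m <- sample_cycle_params(2, seed = 3)
  expect_equal(pair_loglik(m, c(1, 2), 8, 11),
               pair_loglik(m, c(2, 1), 11, 8))

  ll256 <- pair_loglik(m, c(1, 2), 8, 11, n_quad = 256)
  ll2048 <- pair_loglik(m, c(1, 2), 8, 11, n_quad = 2048)
  expect_lt(abs(ll256 - ll2048), 1e-8)

  # brute-force fine-grid oracle for the marginalized likelihood
  tt <- (seq_len(1e6) - 0.5) / 1e6
  mu <- eval_mean_trajectory(m, tt)
  lik <- mean(dnorm(8, mu[1, ], m$noise_sd[1]) * dnorm(11, mu[2, ], m$noise_sd[2]))
  expect_lt(abs(pair_loglik(m, c(1, 2), 8, 11) - log(lik)), 1e-6)
})

test_that("the total likelihood is additive and agrees with the reference path", {
  m <- sample_cycle_params(3, seed = 4)
  d <- simulate_continuous(m, n_obs_per_pair = 40, seed = 5)
  expect_equal(total_loglik(m, d[0, ]), 0)

  split_ll <- total_loglik(m, d[1:50, ]) + total_loglik(m, d[-(1:50), ])
  expect_equal(total_loglik(m, d), split_ll, tolerance = 1e-10)

  # compiled kernel vs plain-R pair_loglik
  ref <- 0
  for (key in unique(paste(d$gene_a, d$gene_b))) {
    rows <- paste(d$gene_a, d$gene_b) == key
    pr <- c(d$gene_a[rows][1], d$gene_b[rows][1])
    ref <- ref + sum(pair_loglik(m, pr, d$count_a[rows], d$count_b[rows]))
  }
  expect_equal(total_loglik(m, d), ref, tolerance = 1e-10)

  perturbed <- continuous_cycle_model(
    baseline = m$baseline + 8, amplitude = m$amplitude,
    phase = m$phase + 2, noise_sd = m$noise_sd
  )
  expect_gt(total_loglik(m, d), total_loglik(perturbed, d))
})

test_that("phase initialization resolves hand-checkable geometries", {
  inphase <- continuous_cycle_model(
    baseline = c(10, 10), amplitude = c(5, 5), phase = c(1, 1),
    noise_sd = c(1e-6, 1e-6)
  )
  d <- simulate_continuous(inphase, n_obs_per_pair = 500, seed = 6)
  st <- init_phases(d, method = "a")[[1]]
  expect_equal(abs(cos(st$phase[1] - st$phase[2])), 1, tolerance = 1e-6)

  anti <- continuous_cycle_model(
    baseline = c(10, 10), amplitude = c(5, 5), phase = c(1, 1 + pi),
    noise_sd = c(1e-6, 1e-6)
  )
  d2 <- simulate_continuous(anti, n_obs_per_pair = 500, seed = 7)
  st2 <- init_phases(d2, method = "a")[[1]]
  expect_equal(cos(st2$phase[1] - st2$phase[2]), -1, tolerance = 1e-6)

  # noiseless in-phase triple: method (b) recovers equal phases
  triple <- continuous_cycle_model(
    baseline = rep(10, 3), amplitude = rep(5, 3), phase = rep(0.7, 3),
    noise_sd = rep(1e-6, 3)
  )
  d3 <- simulate_continuous(triple, n_obs_per_pair = 300, seed = 8)
  stb <- init_phases(d3, method = "b")$b
  rel <- stb$phase - stb$phase[1]
  expect_lt(max(abs(sin(rel))), 1e-6)
})

test_that("method (b) phases beat random phase vectors on the concordance objective", {
  m <- sample_cycle_params(5, noise_max = 2, seed = 9)
  d <- simulate_continuous(m, n_obs_per_pair = 200, seed = 10)
  stats <- snapdyn:::pair_summary_stats(d)
  stb <- init_phases(d, method = "b")$b
  obj_b <- snapdyn:::phase_concordance(stb$phase, stats$rho)
  rand_obj <- with_seed_local(11, {
    vapply(1:100, function(k) {
      snapdyn:::phase_concordance(runif(5, 0, 2 * pi), stats$rho)
    }, numeric(1))
  })
  expect_gte(obj_b, max(rand_obj))
})

test_that("initialization rejects constant genes by name", {
  d <- make_pair_obs(
    list(list(gene_a = "gA", gene_b = "gB",
              count_a = rep(5, 10), count_b = rnorm(10, 8))),
    regime = "continuous"
  )
  expect_error(init_phases(d), "gA")
})

test_that("low-noise data are reconstructed almost exactly", {
  truth <- continuous_cycle_model(
    baseline = c(12, 15, 9), amplitude = c(5, 6, 4),
    phase = c(0.2, 2.3, 4.0), noise_sd = rep(0.05, 3)
  )
  d <- simulate_continuous(truth, n_obs_per_pair = 150, seed = 12)
  fit <- fit_continuous(d, seed = 13)
  expect_lt(reconstruction_error_continuous(truth, fit$model), 0.01)
  expect_gte(fit$log_likelihood, max(fit$starts$log_likelihood))
})

test_that("the fitted likelihood is invariant under phase shift and reflection", {
  m <- sample_cycle_params(3, noise_max = 2, seed = 14)
  d <- simulate_continuous(m, n_obs_per_pair = 60, seed = 15)
  fit <- fit_continuous(d, seed = 16)
  mod <- fit$model
  shifted <- continuous_cycle_model(mod$baseline, mod$amplitude,
                                    mod$phase + 1.77, mod$noise_sd)
  reflected <- continuous_cycle_model(mod$baseline, mod$amplitude,
                                      -mod$phase, mod$noise_sd)
  expect_equal(total_loglik(shifted, d), fit$log_likelihood, tolerance = 1e-9)
  expect_equal(total_loglik(reflected, d), fit$log_likelihood, tolerance = 1e-9)
})

test_that("the reconstruction error quotients out the unidentifiable symmetries", {
  m <- sample_cycle_params(4, seed = 17)
  expect_equal(reconstruction_error_continuous(m, m), 0)

  shifted <- continuous_cycle_model(
    m$baseline, m$amplitude, m$phase + 2 * pi / 3, m$noise_sd
  )
  expect_lt(reconstruction_error_continuous(m, shifted), 1e-6)

  reflected <- continuous_cycle_model(
    m$baseline, m$amplitude, -m$phase, m$noise_sd
  )
  expect_lt(reconstruction_error_continuous(m, reflected), 1e-6)

  flat <- continuous_cycle_model(c(10, 10), c(0, 0), c(0, 0), c(1, 1))
  doubled <- continuous_cycle_model(c(20, 10), c(0, 0), c(0, 0), c(1, 1))
  expect_equal(reconstruction_error_continuous(flat, doubled), 1 / sqrt(2))
})

test_that("held-out log-likelihoods are finite and reproducible", {
  truth <- continuous_cycle_model(
    baseline = c(12, 15), amplitude = c(5, 6), phase = c(0.2, 2.3),
    noise_sd = c(1, 1)
  )
  d <- simulate_continuous(truth, n_obs_per_pair = 40, seed = 18)
  h1 <- holdout_loglik(d, n_holdout = 2, seed = 19)
  h2 <- holdout_loglik(d, n_holdout = 2, seed = 19)
  expect_equal(h1, h2)
  expect_true(all(is.finite(h1$holdout_loglik)))
})
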