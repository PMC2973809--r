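sim_est <- function(model, n_obs, seed) {
  estimate_moments(simulate_bursty(model, n_obs_per_pair = n_obs, seed = seed))
}

test_that("the covariance likelihood matches its closed-form extremes", {
  m <- sample_burst_cycle_params(3, seed = 1)
  est <- sim_est(m, 2000, seed = 2)
  theory <- exact_moments(m)$cov

  # perfect agreement: likelihood is the normalization sum
  est_perfect <- est
  idx <- snapdyn:::moment_pair_index(est, est$genes$gene)
  est_perfect$pairs$c_hat <- theory[idx]
  expect_equal(cov_loglik(theory, est_perfect),
               sum(-0.5 * log(2 * pi * est$pairs$c_var)))

  # a one-standard-deviation residual on one pair costs exactly 1/2
  est_z1 <- est_perfect
  est_z1$pairs$c_hat[1] <- est_z1$pairs$c_hat[1] + sqrt(est_z1$pairs$c_var[1])
  expect_equal(cov_loglik(theory, est_z1),
               cov_loglik(theory, est_perfect) - 0.5)

  # brute-force product of densities
  direct <- sum(log(dnorm(est$pairs$c_hat, theory[idx],
                          sqrt(est$pairs$c_var))))
  expect_equal(cov_loglik(theory, est), direct)
})

test_that("fitted cyclic models pin the means exactly", {
  m <- sample_burst_cycle_params(5, amplitude_locked = TRUE, seed = 3)
  est <- sim_est(m, 2000, seed = 4)
  fit <- fit_cycle_bursty(est, amplitude_locked = TRUE, seed = 5)
  expect_equal(unname(exact_moments(fit$model)$mean), est$genes$p_hat,
               tolerance = 1e-12)
  expect_true(fit$pinned_means)
})

test_that("locked-cycle phases are recovered up to shift and reflection", {
  m <- sample_burst_cycle_params(8, amplitude_locked = TRUE, seed = 6)
  est <- sim_est(m, 5000, seed = 7)
  fit <- fit_cycle_bursty(est, amplitude_locked = TRUE, seed = 8)
  conc <- vapply(c(1, -1), function(s) {
    Mod(mean(exp(1i * (s * fit$model$phase[, 1] - m$phase[, 1]))))
  }, numeric(1))
  expect_gt(max(conc), 0.9)
  expect_gte(fit$restart_agreement, 0.8)
})

test_that("the bursty likelihood is invariant under the cycle degeneracies", {
  m <- sample_burst_cycle_params(5, seed = 9)
  est <- sim_est(m, 3000, seed = 10)
  base <- cov_loglik(exact_moments(m)$cov, est)
  shift <- burst_cycle_model(m$mean_prob, m$amplitude, m$phase + 0.9)
  refl <- burst_cycle_model(m$mean_prob, m$amplitude, -m$phase)
  expect_equal(cov_loglik(exact_moments(shift)$cov, est), base,
               tolerance = 1e-9)
  expect_equal(cov_loglik(exact_moments(refl)$cov, est), base,
               tolerance = 1e-9)
})

test_that("under-identified cyclic configurations are rejected with guidance", {
  m <- sample_burst_cycle_params(4, seed = 11)
  est <- sim_est(m, 1000, seed = 12)
  expect_error(fit_cycle_bursty(est, amplitude_locked = FALSE),
               "lock the amplitudes")
  expect_error(fit_cycle_bursty(est, n_harmonics = 2), "triplet")
})

test_that("global noise is recovered near its true level", {
  m <- sample_burst_cycle_params(8, amplitude_locked = TRUE,
                                 global_noise_sd = 0.55, seed = 13)
  est <- sim_est(m, 10000, seed = 14)
  fit <- fit_cycle_bursty(est, amplitude_locked = TRUE,
                          global_noise = "fit", seed = 15)
  expect_gt(fit$fitted_global_noise, 0.35)
  expect_lt(fit$fitted_global_noise, 0.75)
})

test_that("switch fits recover strongly separated states", {
  sw <- sample_switch_params(6, min_separation = 0.4, seed = 16)
  d <- simulate_switch(sw, n_obs_per_pair = 1e4, seed = 17)
  est <- estimate_moments(d)
  fit <- fit_switch(est, p1 = 0.5, seed = 18)
  expect_lt(reconstruction_error_switch(sw, fit$model), 0.1)
  expect_equal(unname(exact_moments(fit$model)$mean), est$genes$p_hat,
               tolerance = 1e-12)
  expect_gte(fit$restart_agreement, 0.8)
  # reported labeling has the more active state first
  expect_gte(mean(fit$model$burst_prob[, 1]),
             mean(fit$model$burst_prob[, 2]))
})

test_that("switch likelihood is invariant under state relabeling", {
  sw <- sample_switch_params(4, state_prob = c(0.3, 0.7), seed = 19)
  d <- simulate_switch(sw, n_obs_per_pair = 2000, seed = 20)
  est <- estimate_moments(d)
  swapped <- switch_model(rev(sw$state_prob), sw$burst_prob[, 2:1])
  expect_equal(cov_loglik(exact_moments(swapped)$cov, est),
               cov_loglik(exact_moments(sw)$cov, est),
               tolerance = 1e-9)
})

test_that("switch fitting validates its inputs", {
  sw <- sample_switch_params(3, seed = 21)
  est <- sim_est_switch <- estimate_moments(
    simulate_switch(sw, n_obs_per_pair = 500, seed = 22)
  )
  expect_error(fit_switch(est, p1 = 0), "p1")
  expect_error(fit_switch(est, n_states = 3, p1 = 0.5), "2-state")
  expect_error(fit_switch(est), "p1")
})

test_that("the switch reconstruction error matches hand-computed values", {
  truth <- switch_model(c(0.5, 0.5), cbind(0.8, 0.2))
  expect_equal(reconstruction_error_switch(truth, truth), 0)

  swapped <- switch_model(c(0.5, 0.5), cbind(0.2, 0.8))
  expect_equal(reconstruction_error_switch(truth, swapped), 0)

  est <- switch_model(c(0.5, 0.5), cbind(0.7, 0.3))
  expect_equal(reconstruction_error_switch(truth, est), 1 / 3)

  flat <- switch_model(c(0.5, 0.5), cbind(c(0.5, 0.6), c(0.5, 0.2)))
  expect_warning(
    d <- reconstruction_error_switch(
      flat,
      switch_model(c(0.5, 0.5), cbind(c(0.5, 0.6), c(0.5, 0.2)))
    ),
    "zero state-to-state variation"
  )
  expect_equal(d, 0)
})
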