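# Maximum-likelihood reconstruction in the bursty regime, operating on the
# measurable moments (pooled burst frequencies + pairwise covariance
# estimates with uncertainties) rather than raw counts.

#' Gaussian log-likelihood of observed covariances under a model
#'
#' Since different pairs are measured in different cells, the pairwise
#' covariance estimates are independent, and each is approximately
#' Gaussian about the model covariance with the sampling variance
#' estimated by [estimate_cov_variance()].  The log-likelihood is
#' \eqn{\sum_{(ij)} \log N(\hat c_{ij};\, c_{ij}(\theta), \sigma^2_{ij})}
#' over the observed pairs.
#'
#' @param theory_cov a full covariance matrix with gene dimnames, or a
#'   `moment_set` from [exact_moments()].
#' @param est a `moment_estimates` object.
#' @return The log-likelihood (a single number).
#' @export
cov_loglik <- function(theory_cov, est) {
  if (inherits(theory_cov, "moment_set")) theory_cov <- theory_cov$cov
  genes <- est$genes$gene
  if (is.null(dimnames(theory_cov))) {
    if (nrow(theory_cov) != length(genes)) {
      abort("`theory_cov` dimension does not match the estimated genes")
    }
    dimnames(theory_cov) <- list(genes, genes)
  }
  idx <- moment_pair_index(est, rownames(theory_cov))
  c_theory <- theory_cov[idx]
  sum(dnorm(est$pairs$c_hat, c_theory, sqrt(est$pairs$c_var), log = TRUE))
}

# Pairwise theory covariances for a single-harmonic cycle, vectorized over
# the observed pair index matrix.
cycle_pair_cov <- function(p_bar, amp, phi, sigma_g, idx) {
  ac <- amp * cos(phi)
  as_ <- amp * sin(phi)
  i <- idx[, 1]
  j <- idx[, 2]
  sigma_g^2 * p_bar[i] * p_bar[j] +
    (1 + sigma_g^2) * 0.5 * (ac[i] * ac[j] + as_[i] * as_[j])
}

pair_normal_loglik <- function(c_theory, est) {
  sum(dnorm(est$pairs$c_hat, c_theory, sqrt(est$pairs$c_var), log = TRUE))
}

#' Fit a cyclic burst-probability model to estimated moments
#'
#' Maximum-likelihood reconstruction of a single-harmonic burst cycle.
#' The cycle-averaged means are pinned to the measured \eqn{\hat p_i}
#' exactly (mean estimates are far more precise than covariance
#' estimates, since single bursts vastly outnumber coincidences); the free
#' parameters are the per-gene phases, plus the amplitudes unless
#' `amplitude_locked`, plus the global-noise amplitude \eqn{\sigma_G} when
#' `global_noise = "fit"`.  The covariance likelihood [cov_loglik()] is
#' maximized by bounded quasi-Newton ascent from `n_restarts` uniform
#' random phase initializations, and the best optimum is returned along
#' with the fraction of restarts that reached it.
#'
#' Amplitudes are bounded to \eqn{[0, \min(\hat p_i, 1 - \hat p_i)]} so
#' the fitted (unclipped) probabilities stay inside \eqn{[0, 1]};
#' \eqn{\sigma_G} is optimized on the log scale.
#'
#' @param est a `moment_estimates` object.
#' @param n_harmonics number of harmonics (only 1 is identifiable from
#'   pairwise data; higher orders are rejected).
#' @param global_noise `"off"` or `"fit"`.
#' @param amplitude_locked if `TRUE`, fit the amplitude-locked family
#'   (\eqn{a_i = \hat p_i}; one free phase per gene).
#' @param n_restarts number of random restarts (default 10).
#' @param seed seed for the restarts.
#' @param agreement_tol log-likelihood tolerance within which a restart is
#'   counted as having reached the best optimum.
#' @return An object of class `bursty_cycle_fit`: list with `model` (a
#'   [burst_cycle_model()] with means pinned to \eqn{\hat p}),
#'   `log_likelihood`, `n_restarts_used`, `restart_agreement`,
#'   `pinned_means = TRUE`, and `fitted_global_noise` (or `NA`).
#' @export
fit_cycle_bursty <- function(est, n_harmonics = 1,
                             global_noise = c("off", "fit"),
                             amplitude_locked = FALSE, n_restarts = 10,
                             seed = NULL, agreement_tol = 0.01) {
  global_noise <- match.arg(global_noise)
  stopifnot(inherits(est, "moment_estimates"))
  if (n_harmonics != 1) {
    abort(paste(
      "pairwise means and covariances cannot constrain more than one",
      "harmonic; refit with n_harmonics = 1 or supply additional",
      "constraints (e.g. triplet measurements)"
    ))
  }
  genes <- est$genes$gene
  n <- length(genes)
  p_bar <- est$genes$p_hat
  idx <- moment_pair_index(est, genes)
  fit_g <- global_noise == "fit"

  n_free <- (n - 1L) + if (amplitude_locked) 0L else n
  n_free <- n_free + as.integer(fit_g)
  if (n_free > nrow(est$pairs)) {
    abort(paste0(
      "under-identified configuration: ", n_free,
      " free parameters but only ", nrow(est$pairs),
      " observed pair covariances; lock the amplitudes",
      " (amplitude_locked = TRUE) or add constraints"
    ))
  }

  amp_max <- pmin(p_bar, 1 - p_bar)
  log_sg_bounds <- c(log(3e-4), log(3))

  unpack <- function(par) {
    phi <- par[1:n]
    k <- n
    if (amplitude_locked) {
      amp <- p_bar
    } else {
      amp <- par[k + 1:n]
      k <- k + n
    }
    sg <- if (fit_g) exp(par[k + 1L]) else 0
    list(phi = phi, amp = amp, sg = sg)
  }
  neg_fn <- function(par) {
    th <- unpack(par)
    -pair_normal_loglik(
      cycle_pair_cov(p_bar, th$amp, th$phi, th$sg, idx), est
    )
  }
  lower <- rep(-Inf, n)
  upper <- rep(Inf, n)
  if (!amplitude_locked) {
    lower <- c(lower, rep(0, n))
    upper <- c(upper, amp_max)
  }
  if (fit_g) {
    lower <- c(lower, log_sg_bounds[1])
    upper <- c(upper, log_sg_bounds[2])
  }

  runs <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      par0 <- runif(n, 0, 2 * pi)
      if (!amplitude_locked) par0 <- c(par0, runif(n, 0.2, 1) * amp_max)
      if (fit_g) par0 <- c(par0, runif(1, log(0.05), log(1)))
      opt <- optim(par0, neg_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7))
      list(par = opt$par, loglik = -opt$value,
           converged = opt$convergence == 0L)
    })
  })
  logliks <- map_dbl(runs, "loglik")
  best <- runs[[which.max(logliks)]]
  th <- unpack(best$par)
  sg_hat <- if (fit_g) {
    if (abs(log(th$sg) - log_sg_bounds[1]) < 1e-9) 0 else th$sg
  } else {
    NA_real_
  }
  model <- burst_cycle_model(
    mean_prob = p_bar,
    amplitude = if (amplitude_locked) NULL else th$amp,
    phase = wrap_phase(th$phi),
    global_noise_sd = if (fit_g) max(0, sg_hat, na.rm = TRUE) else 0,
    amplitude_locked = amplitude_locked, genes = genes
  )
  structure(
    list(
      model = model,
      log_likelihood = max(logliks),
      n_restarts_used = n_restarts,
      restart_agreement = mean(logliks >= max(logliks) - agreement_tol),
      pinned_means = TRUE,
      fitted_global_noise = sg_hat,
      est = est
    ),
    class = "bursty_cycle_fit"
  )
}

#' @export
print.bursty_cycle_fit <- function(x, ...) {
  cat(sprintf(
    "<bursty_cycle_fit> %d genes%s, log-likelihood %.4f (restart agreement %.0f%%)\n",
    x$model$n_genes,
    if (x$model$amplitude_locked) " (amplitude-locked)" else "",
    x$log_likelihood, 100 * x$restart_agreement
  ))
  if (!is.na(x$fitted_global_noise)) {
    cat(sprintf("fitted global noise sd: %.3f\n", x$fitted_global_noise))
  }
  print(tidy(x), ...)
  invisible(x)
}

#' Fit a two-state switch model to estimated moments
#'
#' Assumes the probability `p1` of state 1 is known (pairwise data alone
#' leave one parameter unconstrained for a 2-state switch) and infers the
#' per-state burst probabilities.  Means are pinned exactly: the state-2
#' probability is eliminated as \eqn{q_{i,2} = (\hat p_i - P_1
#' q_{i,1})/(1 - P_1)}, with per-gene box bounds on \eqn{q_{i,1}} keeping
#' both states inside \eqn{[0, 1]}.  [cov_loglik()] is maximized from
#' `n_restarts` random initializations plus the null start
#' \eqn{q_{i,1} = \hat p_i} (both states equal, zero covariance).  The
#' state-swap degeneracy is resolved by labeling so that state 1 has the
#' larger mean burst probability.
#'
#' @param est a `moment_estimates` object.
#' @param n_states number of states (only 2 supported; more states need
#'   additional constraints).
#' @param p1 known probability of state 1, in (0, 1).
#' @param n_restarts number of random restarts (default 10).
#' @param seed seed for the restarts.
#' @param agreement_tol restart-agreement tolerance on the log-likelihood.
#' @return An object of class `switch_fit`: list with `model` (a
#'   [switch_model()]), `log_likelihood`, `n_restarts_used`,
#'   `restart_agreement`, `pinned_means = TRUE`, `states_swapped`.
#' @export
fit_switch <- function(est, n_states = 2, p1, n_restarts = 10, seed = NULL,
                       agreement_tol = 0.01) {
  stopifnot(inherits(est, "moment_estimates"))
  if (n_states != 2) {
    abort("only 2-state switches are identifiable from pairwise data plus a known state probability; more states need explicit extra constraints")
  }
  if (missing(p1) || is.null(p1)) abort("`p1` (the known state-1 probability) is required")
  if (p1 <= 0 || p1 >= 1) abort("`p1` must lie strictly between 0 and 1")
  genes <- est$genes$gene
  n <- length(genes)
  p_hat <- est$genes$p_hat
  bad <- p_hat < 0 | p_hat > 1
  if (any(bad)) {
    abort(paste0("infeasible mean burst probability for gene(s): ",
                 paste(genes[bad], collapse = ", ")))
  }
  idx <- moment_pair_index(est, genes)
  lo <- pmax(0, (p_hat - (1 - p1)) / p1)
  hi <- pmin(1, p_hat / p1)

  q2_of <- function(q1) (p_hat - p1 * q1) / (1 - p1)
  neg_fn <- function(q1) {
    q2 <- q2_of(q1)
    ct <- p1 * q1[idx[, 1]] * q1[idx[, 2]] +
      (1 - p1) * q2[idx[, 1]] * q2[idx[, 2]] -
      p_hat[idx[, 1]] * p_hat[idx[, 2]]
    -pair_normal_loglik(ct, est)
  }

  start_null <- p_hat  # q1 = q2 = p_hat: zero covariance
  runs <- with_seed(seed, {
    starts <- c(list(start_null), lapply(seq_len(n_restarts), function(k) {
      lo + runif(n) * (hi - lo)
    }))
    lapply(starts, function(par0) {
      opt <- optim(par0, neg_fn, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e7))
      list(par = opt$par, loglik = -opt$value,
           converged = opt$convergence == 0L)
    })
  })
  logliks <- map_dbl(runs, "loglik")
  best <- runs[[which.max(logliks)]]
  q1 <- best$par
  q2 <- q2_of(q1)
  swapped <- mean(q1) < mean(q2)
  if (swapped) {
    tmp <- q1
    q1 <- q2
    q2 <- tmp
    p1 <- 1 - p1
  }
  model <- switch_model(c(p1, 1 - p1), cbind(clamp(q1), clamp(q2)),
                        genes = genes)
  structure(
    list(
      model = model,
      log_likelihood = max(logliks),
      n_restarts_used = n_restarts,
      restart_agreement = mean(logliks >= max(logliks) - agreement_tol),
      pinned_means = TRUE,
      states_swapped = swapped,
      est = est
    ),
    class = "switch_fit"
  )
}

#' @export
print.switch_fit <- function(x, ...) {
  cat(sprintf(
    "<switch_fit> %d genes, P1 = %.3f, log-likelihood %.4f (restart agreement %.0f%%)\n",
    x$model$n_genes, x$model$state_prob[1], x$log_likelihood,
    100 * x$restart_agreement
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Reconstruction error between two switch models
#'
#' \deqn{\Delta^2 = \frac1N \sum_i
#'   \frac{\sum_s P_s (\hat q_{i,s} - q_{i,s})^2}
#'        {\sum_s P_s (q_{i,s} - \bar p_i)^2},}
#' the deviation of reconstructed from true per-state burst probabilities,
#' normalized by each gene's state-to-state variation, weighted by the
#' state probabilities, averaged over genes, and minimized over state
#' relabelings (which pairwise data cannot resolve).  Genes with zero
#' state-to-state variation are excluded with a warning.
#'
#' @param true_model,est_model [switch_model()]s with equal gene and state
#'   counts.
#' @return A non-negative number \eqn{\Delta} (0 iff the models agree up
#'   to state relabeling).
#' @export
reconstruction_error_switch <- function(true_model, est_model) {
  stopifnot(inherits(true_model, "switch_model"),
            inherits(est_model, "switch_model"))
  if (true_model$n_genes != est_model$n_genes ||
      true_model$n_states != est_model$n_states) {
    abort("models must have the same numbers of genes and states")
  }
  P <- true_model$state_prob
  q <- true_model$burst_prob
  p_bar <- as.numeric(q %*% P)
  denom <- as.numeric(((q - p_bar)^2) %*% P)
  keep <- denom > 1e-12
  if (!any(keep)) abort("no gene shows state-to-state variation")
  if (!all(keep)) {
    warn(paste0(
      "excluding gene(s) with zero state-to-state variation: ",
      paste(true_model$genes[!keep], collapse = ", ")
    ))
  }
  d2 <- map_dbl(permutations(true_model$n_states), function(perm) {
    qh <- est_model$burst_prob[, perm, drop = FALSE]
    num <- as.numeric(((qh - q)^2) %*% P)
    mean(num[keep] / denom[keep])
  })
  sqrt(max(0, min(d2)))
}
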