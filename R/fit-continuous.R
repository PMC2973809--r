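# Maximum-likelihood reconstruction of harmonic mean-mRNA trajectories from
# continuous-regime pairwise snapshot data.

#' Log-likelihood of pairwise observations under a continuous-regime model
#'
#' The likelihood of a pair observation \eqn{(x_i, x_j)} marginalizes the
#' unknown cell time over the cycle:
#' \deqn{P(x_i, x_j) = \frac1T \int_0^T
#'   N(x_i;\, \mu_i(t), \sigma_i)\, N(x_j;\, \mu_j(t), \sigma_j)\, dt,}
#' approximated by a uniform `n_quad`-point rule (trapezoid on a periodic
#' integrand, hence spectrally accurate) with log-sum-exp stabilization.
#' `pair_loglik()` is a plain-R reference implementation for one pair;
#' `total_loglik()` sums the compiled kernel over every observation in a
#' data set and is what the fitter maximizes.
#'
#' @param model a [continuous_cycle_model()].
#' @param pair length-2 vector of gene indices or names.
#' @param x_i,x_j numeric vectors of counts (same length).
#' @param n_quad number of quadrature points (>= 16; default 128).
#' @return `pair_loglik()`: numeric vector of per-observation
#'   log-likelihoods; `total_loglik()`: a single number (0 for empty data).
#' @export
pair_loglik <- function(model, pair, x_i, x_j, n_quad = 128) {
  stopifnot(inherits(model, "continuous_cycle_model"), length(pair) == 2L)
  if (n_quad < 16) abort("`n_quad` must be at least 16")
  if (length(x_i) != length(x_j)) abort("`x_i` and `x_j` must have equal length")
  if (is.character(pair)) pair <- match(pair, model$genes)
  if (anyNA(pair)) abort("unknown gene in `pair`")
  i <- pair[1]
  j <- pair[2]
  tt <- model$period * (seq_len(n_quad) - 1L) / n_quad
  mu <- eval_mean_trajectory(model, tt)
  li <- outer(x_i, mu[i, ], function(x, m) {
    dnorm(x, m, model$noise_sd[i], log = TRUE)
  })
  lj <- outer(x_j, mu[j, ], function(x, m) {
    dnorm(x, m, model$noise_sd[j], log = TRUE)
  })
  row_logsumexp(li + lj) - log(n_quad)
}

#' @rdname pair_loglik
#' @param data a `pair_obs` tibble (regime `"continuous"`).
#' @export
total_loglik <- function(model, data, n_quad = 128) {
  stopifnot(inherits(model, "continuous_cycle_model"))
  if (nrow(data) == 0L) {
    return(0)
  }
  ia <- match(data$gene_a, model$genes)
  ib <- match(data$gene_b, model$genes)
  if (anyNA(ia) || anyNA(ib)) abort("data contain genes not in the model")
  cont_loglik_cpp(
    model$baseline, model$amplitude, model$phase, model$noise_sd,
    ia, ib, data$count_a, data$count_b, as.integer(n_quad), model$period,
    FALSE
  )$loglik
}

# Per-gene summary statistics pooled over both observation roles, plus the
# per-pair Pearson correlation matrix (diagonal 1, unobserved pairs 0).
pair_summary_stats <- function(data) {
  genes <- pair_obs_genes(data)
  n <- length(genes)
  pooled <- pooled_counts(data, genes)
  mean_i <- vapply(pooled, mean, numeric(1))
  sd_i <- vapply(pooled, sd, numeric(1))
  if (any(!is.finite(sd_i)) || any(sd_i == 0)) {
    bad <- genes[!is.finite(sd_i) | sd_i == 0]
    abort(paste0("gene(s) with zero variance: ", paste(bad, collapse = ", ")))
  }
  rho <- diag(n)
  pairs <- as_tibble(data) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(rho = cor(.data$count_a, .data$count_b), .groups = "drop")
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  rho[cbind(ia, ib)] <- pairs$rho
  rho[cbind(ib, ia)] <- pairs$rho
  rho[!is.finite(rho)] <- 0
  dimnames(rho) <- list(genes, genes)
  list(genes = genes, mean = mean_i, sd = sd_i, rho = rho)
}

phase_concordance <- function(phi, rho) {
  z <- exp(1i * phi)
  (Re(sum(Conj(z) * (rho %*% z))) - nrow(rho)) / 2
}

#' Heuristic parameter starts for the continuous-regime fit
#'
#' Builds full parameter starts for [fit_continuous()]: the baseline start
#' is the per-gene sample mean, and both the amplitude and the noise
#' standard deviation start at half the per-gene sample standard deviation.
#' Phases come from the pairwise Pearson correlation matrix
#' \eqn{\hat\rho}, which for harmonic dynamics approximates
#' \eqn{\cos(\phi_i - \phi_j)}:
#'
#' * method `"a"`: fix a reference gene's phase to zero and assign the
#'   other genes the magnitudes \eqn{|\phi_i| = \arccos \hat\rho_{ri}} of
#'   their relative phases, in decreasing order of correlation; the signs
#'   are unresolved, so two starts are produced (one per reference
#'   gene choice: gene 1, and the gene most correlated overall).
#' * method `"b"`: choose the phases maximizing
#'   \eqn{\sum_{i<j} \hat\rho_{ij} \cos(\phi_i - \phi_j)} -- initialized
#'   from the top two eigenvectors of \eqn{\hat\rho}
#'   (\eqn{\phi_i = \mathrm{atan2}(v_{2,i}, v_{1,i})}) and refined by local
#'   ascent.
#'
#' @param data a `pair_obs` tibble (regime `"continuous"`).
#' @param method `"a"`, `"b"`, or `"both"` (default).
#' @return A named list of [continuous_cycle_model()] starts.
#' @export
init_phases <- function(data, method = c("both", "a", "b")) {
  method <- match.arg(method)
  st <- pair_summary_stats(data)
  n <- length(st$genes)
  if (n < 2L) abort("at least 2 genes with pairwise data are required")
  make_model <- function(phi) {
    continuous_cycle_model(
      baseline = st$mean, amplitude = pmin(st$sd / 2, st$mean),
      phase = wrap_phase(phi), noise_sd = st$sd / 2, genes = st$genes
    )
  }
  starts <- list()
  if (method %in% c("a", "both")) {
    ref2 <- which.max(rowSums(abs(st$rho)) - 1)
    for (ref in unique(c(1L, ref2))) {
      phi <- acos(clamp(st$rho[ref, ], -1, 1))
      phi[ref] <- 0
      starts[[paste0("a_ref", ref)]] <- make_model(phi)
    }
  }
  if (method %in% c("b", "both")) {
    es <- eigen(st$rho, symmetric = TRUE)
    phi0 <- atan2(es$vectors[, 2], es$vectors[, 1])
    opt <- optim(
      phi0,
      fn = function(phi) -phase_concordance(phi, st$rho),
      gr = function(phi) {
        sapply(seq_len(n), function(i) {
          sum(st$rho[i, ] * sin(phi[i] - phi))
        })
      },
      method = "BFGS", control = list(maxit = 500, reltol = 1e-14)
    )
    starts$b <- make_model(opt$par)
  }
  starts
}

#' Fit a harmonic mean-trajectory model by maximum likelihood
#'
#' Maximizes [total_loglik()] by bounded quasi-Newton (L-BFGS-B with the
#' analytic gradient of the quadrature likelihood) from each start:
#' by default the [init_phases()] heuristics, plus any user-supplied
#' models in `extra_starts` and `n_random_starts` random-phase restarts.
#' The best local optimum over all starts is returned.  Amplitudes are
#' bounded below by 0 and noise standard deviations by a small positive
#' floor; fitted phases are reported modulo \eqn{2\pi}.  Only the
#' single-harmonic family is implemented.
#'
#' The zero-flooring of simulated counts is ignored by the Gaussian
#' likelihood (a documented approximation, mild unless means sit within a
#' couple of noise standard deviations of zero).
#'
#' @param data a `pair_obs` tibble, regime `"continuous"`.
#' @param n_harmonics number of harmonics (only 1 supported).
#' @param starts `"heuristic"` (default) or `"none"` (use only
#'   `extra_starts`/random starts).
#' @param extra_starts optional named list of [continuous_cycle_model()]
#'   starts (e.g. the true model, for benchmarking).
#' @param n_random_starts number of additional random-phase starts.
#' @param n_quad quadrature points for the likelihood (default 128).
#' @param seed seed for the random starts.
#' @param maxit maximum L-BFGS-B iterations per start.
#' @return An object of class `continuous_fit`: list with elements `model`
#'   (the best-likelihood [continuous_cycle_model()]), `log_likelihood`,
#'   `starts` (tibble of per-start results), `n_quad`.
#' @export
fit_continuous <- function(data, n_harmonics = 1,
                           starts = c("heuristic", "none"),
                           extra_starts = NULL, n_random_starts = 0,
                           n_quad = 128, seed = NULL, maxit = 500) {
  starts <- match.arg(starts)
  if (n_harmonics != 1) {
    abort("only the single-harmonic family is implemented")
  }
  if (!identical(pair_obs_regime(data), "continuous")) {
    abort("`data` must be continuous-regime observations")
  }
  start_list <- list()
  if (starts == "heuristic") {
    start_list <- init_phases(data, method = "both")
  }
  if (!is.null(extra_starts)) {
    nm <- names(extra_starts) %||% paste0("user", seq_along(extra_starts))
    names(extra_starts) <- nm
    start_list <- c(start_list, extra_starts)
  }
  if (n_random_starts > 0) {
    st <- pair_summary_stats(data)
    rand <- with_seed(seed, {
      lapply(seq_len(n_random_starts), function(k) {
        continuous_cycle_model(
          baseline = st$mean, amplitude = pmin(st$sd / 2, st$mean),
          phase = runif(length(st$genes), 0, 2 * pi),
          noise_sd = st$sd / 2, genes = st$genes
        )
      })
    })
    names(rand) <- paste0("random", seq_len(n_random_starts))
    start_list <- c(start_list, rand)
  }
  if (length(start_list) == 0) abort("no starts available")

  genes <- start_list[[1]]$genes
  n <- length(genes)
  ia <- match(data$gene_a, genes)
  ib <- match(data$gene_b, genes)
  if (anyNA(ia) || anyNA(ib)) abort("data contain genes not in the starts")
  period <- start_list[[1]]$period
  xa <- data$count_a
  xb <- data$count_b

  sigma_floor <- 1e-3
  lower <- c(rep(1e-8, n), rep(0, n), rep(-Inf, n), rep(sigma_floor, n))
  upper <- rep(Inf, 4L * n)

  neg_fn <- function(par) {
    -cont_loglik_cpp(
      par[1:n], par[n + 1:n], par[2 * n + 1:n], par[3 * n + 1:n],
      ia, ib, xa, xb, as.integer(n_quad), period, FALSE
    )$loglik
  }
  neg_gr <- function(par) {
    -cont_loglik_cpp(
      par[1:n], par[n + 1:n], par[2 * n + 1:n], par[3 * n + 1:n],
      ia, ib, xa, xb, as.integer(n_quad), period, TRUE
    )$grad
  }

  results <- map(start_list, function(m0) {
    par0 <- c(m0$baseline, m0$amplitude, m0$phase, pmax(m0$noise_sd, sigma_floor))
    opt <- optim(par0, neg_fn, neg_gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 4.5e7))
    list(par = opt$par, loglik = -opt$value,
         converged = opt$convergence == 0L)
  })

  logliks <- map_dbl(results, "loglik")
  best <- results[[which.max(logliks)]]
  par <- best$par
  model <- continuous_cycle_model(
    baseline = par[1:n],
    amplitude = pmin(par[n + 1:n], par[1:n]),
    phase = wrap_phase(par[2 * n + 1:n]),
    noise_sd = par[3 * n + 1:n], period = period, genes = genes
  )
  structure(
    list(
      model = model,
      log_likelihood = max(logliks),
      starts = tibble(
        label = names(start_list),
        log_likelihood = logliks,
        converged = map_dbl(results, function(r) r$converged) > 0,
        best = logliks == max(logliks)
      ),
      n_quad = n_quad,
      n_obs = nrow(data)
    ),
    class = "continuous_fit"
  )
}

#' @export
print.continuous_fit <- function(x, ...) {
  cat(sprintf(
    "<continuous_fit> %d genes, log-likelihood %.4f (%d starts, best: %s)\n",
    x$model$n_genes, x$log_likelihood,
    nrow(x$starts), paste(x$starts$label[x$starts$best], collapse = ", ")
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Reconstruction error between two continuous-regime trajectory sets
#'
#' The normalized root-mean-square deviation
#' \deqn{\Delta^2 = \frac1N \sum_i \frac{\frac1T\int_0^T
#'   [\hat\mu_i(t) - \mu_i(t)]^2\, dt}{\langle \mu_i \rangle^2},}
#' minimized over the global time shift and time reflection of the
#' estimate, the two symmetries that snapshot data cannot constrain.  For
#' single-harmonic models the integral and the optimal shift are available
#' in closed form.  \eqn{\Delta = 0} iff the trajectories coincide up to
#' those symmetries.
#'
#' @param true_model,est_model [continuous_cycle_model()]s over the same
#'   genes.
#' @return A non-negative number \eqn{\Delta}.
#' @export
reconstruction_error_continuous <- function(true_model, est_model) {
  stopifnot(inherits(true_model, "continuous_cycle_model"),
            inherits(est_model, "continuous_cycle_model"))
  if (true_model$n_genes != est_model$n_genes ||
      !identical(true_model$genes, est_model$genes)) {
    abort("models must describe the same gene set")
  }
  w <- 1 / true_model$baseline^2
  base <- sum(w * ((est_model$baseline - true_model$baseline)^2 +
                     0.5 * est_model$amplitude^2 +
                     0.5 * true_model$amplitude^2))
  # cross term: (1/T) int A-hat A cos(s phihat - phi + theta) dt maximized
  # over the shift angle theta gives |sum_i w_i A-hat_i A_i e^{i delta_i}|
  cross <- vapply(c(1, -1), function(s) {
    z <- w * est_model$amplitude * true_model$amplitude *
      exp(1i * (s * est_model$phase - true_model$phase))
    Mod(sum(z))
  }, numeric(1))
  d2 <- (base - max(cross)) / true_model$n_genes
  sqrt(max(0, d2))
}

#' Mean held-out log-likelihood for model assessment
#'
#' Thin leave-one-out utility: refits the model with single observations
#' held out and reports the mean log-likelihood of the held-out points,
#' which rewards fit quality while penalizing overfitting.  Because a full
#' leave-one-out sweep refits once per observation, a random subset of
#' held-out observations is used.
#'
#' @param data a `pair_obs` tibble, regime `"continuous"`.
#' @param n_holdout number of held-out observations (capped at `nrow(data)`).
#' @param seed seed for the holdout sample.
#' @param ... passed to [fit_continuous()].
#' @return A tibble with the held-out row indices and their log-likelihood
#'   under the model refitted without them.
#' @export
holdout_loglik <- function(data, n_holdout = 10, seed = NULL, ...) {
  n_holdout <- min(n_holdout, nrow(data))
  idx <- with_seed(seed, sample.int(nrow(data), n_holdout))
  ll <- map_dbl(idx, function(i) {
    fit <- fit_continuous(data[-i, , drop = FALSE], ...)
    total_loglik(fit$model, data[i, , drop = FALSE], n_quad = fit$n_quad)
  })
  tibble(row = idx, holdout_loglik = ll)
}
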