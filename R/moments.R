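#' Exact cycle- or state-averaged moments of a model
#'
#' Computes the population mean and between-gene covariance implied by a
#' model, i.e. the quantities a large pairwise snapshot experiment
#' estimates.  For burst models the moments are those of the underlying
#' burst probabilities: conditional on the (hidden) cycle phase and global
#' factor, burst indicators of different genes are independent, so the
#' between-gene indicator covariance equals the covariance of the
#' probabilities themselves.  The diagonal returned here is likewise the
#' variance of the burst probability over the cycle/states -- the low-rank
#' quantity that the missing data diagonal would have to be completed with
#' -- not the Bernoulli indicator variance.
#'
#' Closed forms (no clipping):
#' * single-harmonic cycle: \eqn{m_i = \bar p_i},
#'   \eqn{c_{ij} = \tfrac12 a_i a_j \cos(\phi_i - \phi_j)} (summed over
#'   harmonics for \eqn{H > 1}; distinct harmonics are orthogonal);
#' * with global noise: \eqn{c_{ij} = \sigma_G^2 \bar p_i \bar p_j +
#'   (1 + \sigma_G^2) \sum_h \tfrac12 a_{i,h} a_{j,h}
#'   \cos(\phi_{i,h} - \phi_{j,h})};
#' * switch: \eqn{m_i = \sum_s P_s q_{i,s}},
#'   \eqn{c_{ij} = \sum_s P_s q_{i,s} q_{j,s} - m_i m_j};
#' * continuous cycle: mean `baseline`, covariance
#'   \eqn{\tfrac12 A_i A_j \cos(\phi_i - \phi_j)} plus \eqn{\sigma_i^2} on
#'   the diagonal.
#'
#' The closed forms ignore the \eqn{[0,1]} clipping of burst probabilities
#' (as the model algebra does); `method = "quadrature"` integrates the
#' clipped probabilities on a fine time grid (and, for global noise, over
#' the gamma-distributed global factor by generalized Gauss-Laguerre
#' quadrature, exact for the unclipped moments), so the two methods agree
#' to near machine precision whenever clipping never triggers.
#'
#' @param model a model object.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @param n_quad number of time-grid points for the quadrature path.
#' @param n_quad_g number of Gauss-Laguerre nodes for the global factor.
#' @return An object of class `moment_set`: list with elements `mean`
#'   (named vector) and `cov` (symmetric matrix).
#' @export
#' @examples
#' m <- burst_cycle_model(mean_prob = c(0.2, 0.2), amplitude = c(0.1, 0.1),
#'                        phase = c(0, pi / 2))
#' exact_moments(m)$cov
exact_moments <- function(model, method = c("closed_form", "quadrature"),
                          n_quad = 4096, n_quad_g = 64) {
  method <- match.arg(method)
  UseMethod("exact_moments")
}

#' @export
exact_moments.burst_cycle_model <- function(model,
                                            method = c("closed_form", "quadrature"),
                                            n_quad = 4096, n_quad_g = 64) {
  method <- match.arg(method)
  sg <- model$global_noise_sd
  if (method == "closed_form") {
    m <- model$mean_prob
    cc <- matrix(0, model$n_genes, model$n_genes)
    for (h in seq_len(model$n_harmonics)) {
      ac <- model$amplitude[, h] * cos(model$phase[, h])
      as_ <- model$amplitude[, h] * sin(model$phase[, h])
      cc <- cc + 0.5 * (tcrossprod(ac) + tcrossprod(as_))
    }
    cv <- sg^2 * tcrossprod(m) + (1 + sg^2) * cc
  } else {
    tt <- (seq_len(n_quad) - 0.5) / n_quad * model$period
    if (sg > 0) {
      shape <- 1 / sg^2
      gl <- pracma::gaussLaguerre(n_quad_g, shape - 1)
      g_nodes <- gl$x * sg^2
      g_w <- gl$w / gamma(shape)
    } else {
      g_nodes <- 1
      g_w <- 1
    }
    m <- numeric(model$n_genes)
    e2 <- matrix(0, model$n_genes, model$n_genes)
    for (k in seq_along(g_nodes)) {
      p <- eval_burst_prob(model, tt, global_factor = g_nodes[k])
      m <- m + g_w[k] * rowMeans(p)
      e2 <- e2 + g_w[k] * tcrossprod(p) / n_quad
    }
    cv <- e2 - tcrossprod(m)
  }
  new_moment_set(m, cv, model$genes)
}

#' @export
exact_moments.switch_model <- function(model,
                                       method = c("closed_form", "quadrature"),
                                       n_quad = 4096, n_quad_g = 64) {
  q <- model$burst_prob
  P <- model$state_prob
  m <- as.numeric(q %*% P)
  cv <- q %*% (P * t(q)) - tcrossprod(m)
  new_moment_set(m, cv, model$genes)
}

#' @export
exact_moments.continuous_cycle_model <- function(model,
                                                 method = c("closed_form", "quadrature"),
                                                 n_quad = 4096, n_quad_g = 64) {
  method <- match.arg(method)
  if (method == "closed_form") {
    m <- model$baseline
    ac <- model$amplitude * cos(model$phase)
    as_ <- model$amplitude * sin(model$phase)
    cv <- 0.5 * (tcrossprod(ac) + tcrossprod(as_))
  } else {
    tt <- (seq_len(n_quad) - 0.5) / n_quad * model$period
    mu <- eval_mean_trajectory(model, tt)
    m <- rowMeans(mu)
    cv <- tcrossprod(mu) / n_quad - tcrossprod(m)
  }
  diag(cv) <- diag(cv) + model$noise_sd^2
  new_moment_set(m, cv, model$genes)
}

new_moment_set <- function(mean, cov, genes) {
  cov <- (cov + t(cov)) / 2
  names(mean) <- genes
  dimnames(cov) <- list(genes, genes)
  structure(list(mean = mean, cov = cov), class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> %d genes\n", length(x$mean)))
  cat("mean:\n")
  print(signif(x$mean, 4))
  cat("cov:\n")
  print(signif(x$cov, 4))
  invisible(x)
}

#' @rdname exact_moments
#' @param x a `moment_set`.
#' @param ... unused.
#' @export
tidy.moment_set <- function(x, ...) {
  genes <- names(x$mean)
  idx <- which(upper.tri(x$cov), arr.ind = TRUE)
  tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    cov = x$cov[idx]
  )
}

#' Numerical rank of a symmetric covariance matrix
#'
#' Counts eigenvalues whose magnitude exceeds `rel_tol` times the largest
#' eigenvalue magnitude.  The rank of the exact between-gene covariance
#' identifies the dynamical complexity: \eqn{2H} for a cycle with \eqn{H}
#' harmonics (\eqn{+1} with global noise) and \eqn{S - 1} for an
#' \eqn{S}-state switch.
#'
#' @param cov symmetric numeric matrix.
#' @param rel_tol relative eigenvalue tolerance (default `1e-8`).
#' @return Integer rank (0 for the zero matrix).
#' @export
covariance_rank <- function(cov, rel_tol = 1e-8) {
  if (!is_symmetric_tol(cov)) abort("`cov` must be a symmetric matrix")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev))
  if (mx == 0) {
    return(0L)
  }
  sum(abs(ev) > rel_tol * mx)
}
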