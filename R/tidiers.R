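# broom-style tidiers and ggplot2 visualisations for fitted objects.

#' @rdname fit_continuous
#' @param x a `continuous_fit`.
#' @param ... unused.
#' @export
tidy.continuous_fit <- function(x, ...) tidy(x$model)

#' @rdname fit_continuous
#' @export
glance.continuous_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    n_genes = x$model$n_genes,
    n_obs = x$n_obs,
    n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged),
    best_start = paste(x$starts$label[x$starts$best], collapse = ",")
  )
}

#' @rdname fit_cycle_bursty
#' @param x a `bursty_cycle_fit`.
#' @param ... unused.
#' @export
tidy.bursty_cycle_fit <- function(x, ...) tidy(x$model)

#' @rdname fit_cycle_bursty
#' @export
glance.bursty_cycle_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    n_genes = x$model$n_genes,
    amplitude_locked = x$model$amplitude_locked,
    global_noise_sd = x$fitted_global_noise,
    n_restarts = x$n_restarts_used,
    restart_agreement = x$restart_agreement
  )
}

#' @rdname fit_switch
#' @param x a `switch_fit`.
#' @param ... unused.
#' @export
tidy.switch_fit <- function(x, ...) tidy(x$model)

#' @rdname fit_switch
#' @export
glance.switch_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    n_genes = x$model$n_genes,
    p1 = x$model$state_prob[1],
    n_restarts = x$n_restarts_used,
    restart_agreement = x$restart_agreement
  )
}

model_curve_data <- function(model, n_t = 256) {
  tt <- model$period * (seq_len(n_t) - 1L) / (n_t - 1L)
  if (inherits(model, "continuous_cycle_model")) {
    y <- eval_mean_trajectory(model, tt)
    lab <- "mean mRNA count"
  } else {
    y <- eval_burst_prob(model, tt)
    lab <- "burst probability"
  }
  list(
    df = tibble(
      gene = rep(model$genes, times = length(tt)),
      t = rep(tt, each = model$n_genes),
      value = as.numeric(y)
    ),
    ylab = lab
  )
}

plot_model_curves <- function(model, n_t = 256) {
  cd <- model_curve_data(model, n_t)
  ggplot2::ggplot(cd$df, ggplot2::aes(.data$t, .data$value,
                                      colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle time (periods)", y = cd$ylab, colour = "gene")
}

#' Plot reconstructed trajectories
#'
#' @param object a fitted object or model.
#' @param n_t number of curve points.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.continuous_fit <- function(object, n_t = 256, ...) {
  plot_model_curves(object$model, n_t) +
    ggplot2::ggtitle("Reconstructed mean mRNA trajectories")
}

#' @rdname autoplot.continuous_fit
#' @export
autoplot.continuous_cycle_model <- function(object, n_t = 256, ...) {
  plot_model_curves(object, n_t)
}

#' @rdname autoplot.continuous_fit
#' @export
autoplot.burst_cycle_model <- function(object, n_t = 256, ...) {
  plot_model_curves(object, n_t)
}

#' @rdname autoplot.continuous_fit
#' @export
autoplot.bursty_cycle_fit <- function(object, n_t = 256, ...) {
  plot_model_curves(object$model, n_t) +
    ggplot2::ggtitle("Reconstructed burst-probability cycle")
}

#' Scree plot of a PCA completion
#'
#' Eigenvalues of the diagonal-completed covariance with the
#' rank-inference threshold.
#'
#' @param object a `pca_completion`.
#' @param noise_factor threshold multiplier (see [infer_complexity()]).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pca_completion <- function(object, noise_factor = 5, ...) {
  cx <- infer_complexity(object$eigenvalues, noise_factor)
  df <- tibble(
    index = seq_along(object$eigenvalues),
    eigenvalue = object$eigenvalues
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cx$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "component", y = "eigenvalue",
      title = sprintf("Completed-covariance spectrum (inferred rank %d)",
                      cx$rank)
    )
}

#' Plot cluster activities over the cycle
#'
#' @inheritParams cluster_activity
#' @return A ggplot of \eqn{Q_j(t)} per cluster.
#' @export
plot_cluster_activity <- function(model, clusters, t_grid = NULL) {
  df <- cluster_activity(model, clusters, t_grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$activity,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "cycle time (periods)", y = "cluster activity Q(t)",
                  colour = "cluster")
}

#' Reconstructed versus observed pairwise covariances
#'
#' Diagnostic scatter comparing the covariances implied by a fitted
#' bursty-regime model with the estimates they were fitted to, with
#' one-standard-deviation error bars.
#'
#' @param fit a `bursty_cycle_fit` or `switch_fit`.
#' @param est a `moment_estimates` (defaults to the one stored in the
#'   fit).
#' @return A ggplot.
#' @export
plot_cov_comparison <- function(fit, est = fit$est) {
  theory <- exact_moments(fit$model)$cov
  idx <- moment_pair_index(est, rownames(theory))
  df <- mutate(est$pairs,
               reconstructed = theory[idx],
               se = sqrt(.data$c_var))
  ggplot2::ggplot(df, ggplot2::aes(.data$reconstructed, .data$c_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$c_hat - .data$se,
                                        ymax = .data$c_hat + .data$se),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reconstructed covariance", y = "observed covariance")
}
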