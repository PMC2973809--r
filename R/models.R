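#' Harmonic mean-expression model for the continuous regime
#'
#' Describes per-gene mean mRNA trajectories
#' \eqn{\mu_i(t) = \mu_{0,i} + A_i \cos(2\pi t/T + \phi_i)} with independent
#' Gaussian measurement/expression noise of standard deviation
#' \eqn{\sigma_i} about the mean.  This is the model family used to
#' reconstruct cyclic dynamics when many transcription bursts contribute to
#' each mRNA count, so counts fluctuate continuously about a smooth mean.
#'
#' The period is a pure convention (snapshot data carry no time scale); all
#' phases follow the \eqn{\cos(2\pi t/T + \phi)} sign convention.
#'
#' @param baseline numeric vector of per-gene mean mRNA counts
#'   (\eqn{\mu_{0,i} > 0}).
#' @param amplitude numeric vector of oscillation amplitudes
#'   (\eqn{0 \le A_i \le \mu_{0,i}}, so the mean trajectory stays
#'   non-negative).
#' @param phase numeric vector of phases in radians.
#' @param noise_sd numeric vector of positive noise standard deviations in
#'   mRNA counts.
#' @param period oscillation period (arbitrary units, default 1).
#' @param genes optional character vector of gene names.
#' @return An object of class `continuous_cycle_model`.
#' @export
#' @examples
#' m <- continuous_cycle_model(baseline = c(10, 8), amplitude = c(5, 4),
#'                             phase = c(0, pi / 2), noise_sd = c(1, 1))
#' eval_mean_trajectory(m, 0)
continuous_cycle_model <- function(baseline, amplitude, phase, noise_sd,
                                   period = 1, genes = NULL) {
  n <- length(baseline)
  stopifnot(length(amplitude) == n, length(phase) == n, length(noise_sd) == n)
  if (n < 1L) abort("at least one gene is required")
  if (period <= 0) abort("`period` must be positive")
  if (any(baseline <= 0)) abort("`baseline` must be positive")
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative")
  if (any(amplitude > baseline + 1e-12)) {
    abort("`amplitude` must not exceed `baseline` (mean trajectory must stay non-negative)")
  }
  if (any(noise_sd <= 0)) abort("`noise_sd` must be positive")
  genes <- genes %||% default_gene_names(n)
  structure(
    list(
      n_genes = n, period = period, genes = as.character(genes),
      baseline = as.numeric(baseline), amplitude = as.numeric(amplitude),
      phase = as.numeric(phase), noise_sd = as.numeric(noise_sd)
    ),
    class = "continuous_cycle_model"
  )
}

#' Cyclic burst-probability model for the bursty regime
#'
#' In the bursty regime each count is dominated by at most one recent
#' transcription burst, so the informative quantity is the probability
#' \eqn{p_i(t)} that gene \eqn{i} has a burst present at cycle phase
#' \eqn{t}.  The probability is a truncated Fourier series
#' \deqn{p_i(t) = \bar p_i + \sum_{h=1}^{H} a_{i,h}
#'   \cos(2\pi h t/T + \phi_{i,h}),}
#' optionally scaled by a cell-wide global transcription factor \eqn{G}
#' (mean 1, standard deviation `global_noise_sd`) and clipped to
#' \eqn{[0, 1]} during simulation.
#'
#' With `amplitude_locked = TRUE` the model is the single-harmonic form
#' \eqn{p_i(t) = \bar p_i (1 + \cos(2\pi t/T + \phi_i))}, which touches zero
#' once per cycle and leaves a single free parameter per gene (its phase)
#' once \eqn{\bar p_i} is pinned to the data.
#'
#' @param mean_prob numeric vector of cycle-averaged burst probabilities
#'   \eqn{\bar p_i \in [0, 1]}.
#' @param amplitude vector (one harmonic) or `n_genes x H` matrix of
#'   non-negative harmonic amplitudes.  Ignored when `amplitude_locked`.
#' @param phase vector or `n_genes x H` matrix of phases in radians.
#' @param global_noise_sd standard deviation \eqn{\sigma_G \ge 0} of the
#'   global transcription factor (0 disables global noise).
#' @param amplitude_locked if `TRUE`, force one harmonic with
#'   `amplitude = mean_prob`.
#' @param period oscillation period (default 1).
#' @param genes optional gene names.
#' @return An object of class `burst_cycle_model`.
#' @export
#' @examples
#' m <- burst_cycle_model(mean_prob = c(0.2, 0.3), phase = c(0, pi / 3),
#'                        amplitude_locked = TRUE)
#' eval_burst_prob(m, c(0, 0.25, 0.5))
burst_cycle_model <- function(mean_prob, amplitude = NULL, phase,
                              global_noise_sd = 0, amplitude_locked = FALSE,
                              period = 1, genes = NULL) {
  n <- length(mean_prob)
  if (n < 1L) abort("at least one gene is required")
  if (period <= 0) abort("`period` must be positive")
  if (any(mean_prob < 0 | mean_prob > 1)) abort("`mean_prob` must lie in [0, 1]")
  if (global_noise_sd < 0) abort("`global_noise_sd` must be non-negative")
  phase <- if (is.matrix(phase)) phase else matrix(phase, ncol = 1L)
  if (amplitude_locked) {
    if (ncol(phase) != 1L) {
      abort("an amplitude-locked model has exactly one harmonic")
    }
    amplitude <- matrix(mean_prob, ncol = 1L)
  } else {
    if (is.null(amplitude)) abort("`amplitude` is required unless `amplitude_locked`")
    amplitude <- if (is.matrix(amplitude)) amplitude else matrix(amplitude, ncol = 1L)
  }
  if (nrow(amplitude) != n || nrow(phase) != n || ncol(amplitude) != ncol(phase)) {
    abort("`amplitude` and `phase` must have one row per gene and one column per harmonic")
  }
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative")
  genes <- genes %||% default_gene_names(n)
  structure(
    list(
      n_genes = n, period = period, genes = as.character(genes),
      mean_prob = as.numeric(mean_prob),
      amplitude = unname(amplitude), phase = unname(phase),
      n_harmonics = ncol(amplitude),
      global_noise_sd = global_noise_sd,
      amplitude_locked = isTRUE(amplitude_locked)
    ),
    class = "burst_cycle_model"
  )
}

#' Stochastic switch model
#'
#' All genes jump synchronously among `S` discrete expression states; each
#' fixed cell is in state \eqn{s} with probability \eqn{P_s}, and in state
#' \eqn{s} gene \eqn{i} shows a burst with probability \eqn{q_{i,s}}.
#' Snapshot data can constrain the \eqn{P_s} and \eqn{q_{i,s}} but not the
#' kinetics of switching.
#'
#' @param state_prob numeric vector of state probabilities, summing to 1.
#' @param burst_prob `n_genes x n_states` matrix of per-state burst
#'   probabilities in \eqn{[0, 1]}.
#' @param genes optional gene names.
#' @return An object of class `switch_model`.
#' @export
#' @examples
#' sw <- switch_model(state_prob = c(0.5, 0.5),
#'                    burst_prob = cbind(c(0.9, 0.8), c(0.1, 0.2)))
#' exact_moments(sw)
switch_model <- function(state_prob, burst_prob, genes = NULL) {
  burst_prob <- as.matrix(burst_prob)
  S <- length(state_prob)
  if (S < 2L) abort("a switch needs at least 2 states")
  if (abs(sum(state_prob) - 1) > 1e-12) abort("`state_prob` must sum to 1")
  if (any(state_prob < 0 | state_prob > 1)) abort("`state_prob` must lie in [0, 1]")
  if (ncol(burst_prob) != S) abort("`burst_prob` needs one column per state")
  if (any(burst_prob < 0 | burst_prob > 1)) abort("`burst_prob` must lie in [0, 1]")
  n <- nrow(burst_prob)
  genes <- genes %||% default_gene_names(n)
  structure(
    list(
      n_genes = n, n_states = S, genes = as.character(genes),
      state_prob = as.numeric(state_prob), burst_prob = unname(burst_prob)
    ),
    class = "switch_model"
  )
}

#' Evaluate the mean mRNA trajectory of a continuous-regime model
#'
#' @param model a [continuous_cycle_model()].
#' @param t numeric vector of times.
#' @return A numeric matrix with one row per gene and one column per time
#'   (dropped to a vector for a single time point).
#' @export
eval_mean_trajectory <- function(model, t) {
  stopifnot(inherits(model, "continuous_cycle_model"))
  ang <- outer(rep(2 * pi / model$period, model$n_genes), t) + model$phase
  mu <- model$baseline + model$amplitude * cos(ang)
  rownames(mu) <- model$genes
  if (length(t) == 1L) mu[, 1L] else mu
}

#' Evaluate burst probabilities of a cyclic burst model
#'
#' Returns \eqn{\mathrm{clip}(g \cdot [\bar p_i + \sum_h a_{i,h}
#' \cos(2\pi h t/T + \phi_{i,h})], 0, 1)} per gene.  The clipping rule
#' mirrors the simulator: a nominal probability above one generates a burst
#' with probability one.
#'
#' @param model a [burst_cycle_model()].
#' @param t numeric vector of times.
#' @param global_factor non-negative global transcription factor
#'   \eqn{g} (default 1).
#' @return Matrix of probabilities (genes x times), or a vector for a single
#'   time point.
#' @export
eval_burst_prob <- function(model, t, global_factor = 1) {
  stopifnot(inherits(model, "burst_cycle_model"))
  if (any(global_factor < 0)) abort("`global_factor` must be non-negative")
  p <- matrix(model$mean_prob, model$n_genes, length(t))
  for (h in seq_len(model$n_harmonics)) {
    ang <- outer(rep(2 * pi * h / model$period, model$n_genes), t) +
      model$phase[, h]
    p <- p + model$amplitude[, h] * cos(ang)
  }
  p <- clamp(p * global_factor)
  rownames(p) <- model$genes
  if (length(t) == 1L) p[, 1L] else p
}

#' @export
print.continuous_cycle_model <- function(x, ...) {
  cat(sprintf(
    "<continuous_cycle_model> %d genes, period %g\n", x$n_genes, x$period
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.burst_cycle_model <- function(x, ...) {
  cat(sprintf(
    "<burst_cycle_model> %d genes, %d harmonic(s)%s%s\n",
    x$n_genes, x$n_harmonics,
    if (x$amplitude_locked) ", amplitude-locked" else "",
    if (x$global_noise_sd > 0) {
      sprintf(", global noise sd %.3g", x$global_noise_sd)
    } else {
      ""
    }
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.switch_model <- function(x, ...) {
  cat(sprintf(
    "<switch_model> %d genes, %d states (P = %s)\n",
    x$n_genes, x$n_states, paste(signif(x$state_prob, 3), collapse = ", ")
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname continuous_cycle_model
#' @param x a model object.
#' @param ... unused.
#' @export
tidy.continuous_cycle_model <- function(x, ...) {
  tibble(
    gene = x$genes, baseline = x$baseline, amplitude = x$amplitude,
    phase = x$phase, noise_sd = x$noise_sd
  )
}

#' @rdname burst_cycle_model
#' @param x a model object.
#' @param ... unused.
#' @export
tidy.burst_cycle_model <- function(x, ...) {
  out <- tidyr::crossing(
    gene = factor(x$genes, levels = x$genes),
    harmonic = seq_len(x$n_harmonics)
  )
  out <- arrange(out, .data$gene, .data$harmonic)
  out$mean_prob <- rep(x$mean_prob, each = x$n_harmonics)
  out$amplitude <- as.numeric(t(x$amplitude))
  out$phase <- as.numeric(t(x$phase))
  out$gene <- as.character(out$gene)
  out
}

#' @rdname switch_model
#' @param x a model object.
#' @param ... unused.
#' @export
tidy.switch_model <- function(x, ...) {
  out <- tidyr::crossing(
    gene = factor(x$genes, levels = x$genes), state = seq_len(x$n_states)
  )
  out <- arrange(out, .data$gene, .data$state)
  out$state_prob <- x$state_prob[out$state]
  out$burst_prob <- as.numeric(t(x$burst_prob))
  out$gene <- as.character(out$gene)
  out
}
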