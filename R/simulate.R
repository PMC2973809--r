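# Synthetic pairwise snapshot data for all model families.  The generators
# define the study conditions used throughout the tests: parameter ranges
# follow the stated construction rules (positivity of mRNA levels,
# significant oscillation amplitudes, burst probabilities that stay inside
# [0, 1] before clipping).

#' Draw a random continuous-regime cycle model
#'
#' Per gene: \eqn{A_i = 5(1 + u_i)}, \eqn{\mu_{0,i} = A_i(1 + u_i')} with
#' \eqn{u, u' \sim U(0,1)} (which guarantees
#' \eqn{\mu_{0,i} \ge A_i}, i.e. a non-negative mean trajectory, while
#' keeping oscillation amplitudes comparable to the baseline), phases
#' uniform on \eqn{[0, 2\pi)}, and noise standard deviations uniform on
#' \eqn{(0, \sigma_{\max}]}.
#'
#' @param n_genes number of genes (>= 2).
#' @param noise_max upper bound of the per-gene noise standard deviation,
#'   in mRNA counts (default 5, comparable to the smallest amplitude).
#' @param seed optional integer seed; the draw is deterministic given the
#'   seed and leaves the caller's RNG stream untouched.
#' @return A [continuous_cycle_model()].
#' @export
sample_cycle_params <- function(n_genes, noise_max = 5, seed = NULL) {
  if (n_genes < 2L) abort("`n_genes` must be at least 2")
  if (noise_max <= 0) abort("`noise_max` must be positive")
  with_seed(seed, {
    amplitude <- 5 * (1 + runif(n_genes))
    baseline <- amplitude * (1 + runif(n_genes))
    phase <- runif(n_genes, 0, 2 * pi)
    noise_sd <- runif(n_genes, 0, noise_max)
    noise_sd[noise_sd == 0] <- noise_max * 1e-6
    continuous_cycle_model(baseline, amplitude, phase, noise_sd)
  })
}

#' Draw a random bursty-regime cycle model
#'
#' Mean burst probabilities are uniform on `mean_prob_range` (default
#' \eqn{[0.05, 0.35]}, the range typical of thresholded FISH data); in the
#' free-amplitude variant each amplitude is
#' \eqn{a_i = \bar p_i (0.5 + 0.5 u_i)} so the unclipped probability stays
#' inside \eqn{[0, 1]} while oscillating with significant amplitude; the
#' amplitude-locked variant sets \eqn{a_i = \bar p_i}.  Phases are uniform
#' on \eqn{[0, 2\pi)}.
#'
#' @param n_genes number of genes (>= 2).
#' @param amplitude_locked draw the amplitude-locked family.
#' @param global_noise_sd global-noise standard deviation \eqn{\sigma_G}.
#' @param mean_prob_range range for \eqn{\bar p_i}.
#' @param seed optional integer seed.
#' @return A [burst_cycle_model()].
#' @export
sample_burst_cycle_params <- function(n_genes, amplitude_locked = FALSE,
                                      global_noise_sd = 0,
                                      mean_prob_range = c(0.05, 0.35),
                                      seed = NULL) {
  if (n_genes < 2L) abort("`n_genes` must be at least 2")
  with_seed(seed, {
    p <- runif(n_genes, mean_prob_range[1], mean_prob_range[2])
    phase <- runif(n_genes, 0, 2 * pi)
    if (amplitude_locked) {
      burst_cycle_model(p, phase = phase, amplitude_locked = TRUE,
                        global_noise_sd = global_noise_sd)
    } else {
      a <- p * (0.5 + 0.5 * runif(n_genes))
      burst_cycle_model(p, amplitude = a, phase = phase,
                        global_noise_sd = global_noise_sd)
    }
  })
}

#' Draw a random switch model
#'
#' Per-state burst probabilities are uniform on \eqn{[0, 1]}.  With
#' `min_separation > 0` (two-state models) each gene's row is redrawn until
#' \eqn{|q_{i,1} - q_{i,2}|} exceeds the floor, so that every gene is
#' informative about the hidden state.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_states number of states (default 2).
#' @param state_prob state probabilities (default uniform).
#' @param min_separation minimum \eqn{|q_{i,1} - q_{i,2}|} (2-state only).
#' @param seed optional integer seed.
#' @return A [switch_model()].
#' @export
sample_switch_params <- function(n_genes, n_states = 2, state_prob = NULL,
                                 min_separation = 0, seed = NULL) {
  if (n_genes < 2L) abort("`n_genes` must be at least 2")
  state_prob <- state_prob %||% rep(1 / n_states, n_states)
  with_seed(seed, {
    q <- matrix(runif(n_genes * n_states), n_genes, n_states)
    if (min_separation > 0) {
      if (n_states != 2L) {
        abort("`min_separation` is only supported for 2-state switches")
      }
      for (i in seq_len(n_genes)) {
        while (abs(q[i, 1] - q[i, 2]) < min_separation) {
          q[i, ] <- runif(2)
        }
      }
    }
    switch_model(state_prob, q)
  })
}

new_pair_obs <- function(df, genes, regime, model = NULL, seed = NULL) {
  out <- as_tibble(df)
  attr(out, "genes") <- genes
  attr(out, "regime") <- regime
  attr(out, "true_model") <- model
  attr(out, "seed") <- seed
  class(out) <- c("pair_obs", class(out))
  out
}

#' @export
`[.pair_obs` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("gene_a", "gene_b", "count_a", "count_b") %in% names(out))) {
    attr(out, "genes") <- attr(x, "genes")
    attr(out, "regime") <- attr(x, "regime")
    attr(out, "true_model") <- attr(x, "true_model")
    attr(out, "thresholds") <- attr(x, "thresholds")
    class(out) <- unique(c("pair_obs", class(out)))
  }
  out
}

#' @export
print.pair_obs <- function(x, ...) {
  cat(sprintf(
    "<pair_obs> regime %s: %d genes, %d pairs, %d observations\n",
    pair_obs_regime(x), length(pair_obs_genes(x)),
    nrow(distinct(as_tibble(x)[c("gene_a", "gene_b")])), nrow(x)
  ))
  NextMethod()
}

#' Accessors for pairwise observation sets
#'
#' A pairwise observation set is a tibble with columns `cell_id`, `gene_a`,
#' `gene_b`, `count_a`, `count_b` -- one row per fixed cell, probed for one
#' gene pair -- plus attributes recording the gene universe, the data
#' regime (`continuous`, `bursty_binary`, or `bursty_count`), and, for
#' simulated data, the generating model.
#'
#' @param data a `pair_obs` tibble.
#' @return `pair_obs_genes()` the gene names; `pair_obs_regime()` the
#'   regime tag; `pair_obs_model()` the generating model or `NULL`.
#' @export
pair_obs_genes <- function(data) {
  attr(data, "genes") %||% sort(unique(c(data$gene_a, data$gene_b)))
}

#' @rdname pair_obs_genes
#' @export
pair_obs_regime <- function(data) attr(data, "regime") %||% "unknown"

#' @rdname pair_obs_genes
#' @export
pair_obs_model <- function(data) attr(data, "true_model")

simulate_frame <- function(genes, pm, n_obs_per_pair) {
  n_pairs <- nrow(pm)
  tibble(
    cell_id = seq_len(n_pairs * n_obs_per_pair),
    pair = rep(seq_len(n_pairs), each = n_obs_per_pair),
    ia = rep(pm[, 1], each = n_obs_per_pair),
    ib = rep(pm[, 2], each = n_obs_per_pair)
  )
}

#' Simulate pairwise snapshots in the continuous regime
#'
#' Each observation fixes one cell at a uniformly random (and unrecorded)
#' cycle time and measures two genes: the mean trajectory value plus
#' independent Gaussian noise, floored at zero (counts cannot be negative;
#' the floor introduces a small positive bias when the mean is within a
#' couple of noise standard deviations of zero).  Times are drawn
#' independently for every cell and every pair.
#'
#' @param model a [continuous_cycle_model()].
#' @param pairs 2-column matrix/data frame of gene index pairs, or `NULL`
#'   for all pairs.
#' @param n_obs_per_pair observations (cells) per pair.
#' @param seed optional integer seed.
#' @return A `pair_obs` tibble, regime `"continuous"`.
#' @export
simulate_continuous <- function(model, pairs = NULL, n_obs_per_pair = 100,
                                seed = NULL) {
  stopifnot(inherits(model, "continuous_cycle_model"))
  if (n_obs_per_pair < 1L) abort("`n_obs_per_pair` must be at least 1")
  pm <- as_pair_matrix(pairs, model$n_genes)
  fr <- simulate_frame(model$genes, pm, n_obs_per_pair)
  with_seed(seed, {
    tt <- runif(nrow(fr), 0, model$period)
    ang <- 2 * pi * tt / model$period
    mu_a <- model$baseline[fr$ia] +
      model$amplitude[fr$ia] * cos(ang + model$phase[fr$ia])
    mu_b <- model$baseline[fr$ib] +
      model$amplitude[fr$ib] * cos(ang + model$phase[fr$ib])
    xa <- pmax(0, mu_a + rnorm(nrow(fr), 0, model$noise_sd[fr$ia]))
    xb <- pmax(0, mu_b + rnorm(nrow(fr), 0, model$noise_sd[fr$ib]))
    new_pair_obs(
      tibble(
        cell_id = fr$cell_id,
        gene_a = model$genes[fr$ia], gene_b = model$genes[fr$ib],
        count_a = xa, count_b = xb
      ),
      genes = model$genes, regime = "continuous", model = model, seed = seed
    )
  })
}

#' Simulate pairwise snapshots in the bursty regime
#'
#' Each cell draws a uniform cycle time and (if the model carries global
#' noise) a single gamma-distributed global factor \eqn{G} with mean 1 and
#' standard deviation \eqn{\sigma_G}, shared by both probed genes -- the
#' sharing is what turns global noise into between-gene covariance.  Each
#' gene then bursts with probability
#' \eqn{\mathrm{clip}(G\,p_i(t), 0, 1)}.  With `output = "counts"` the
#' binary indicators are dressed into mRNA counts with geometric burst
#' sizes (mean `burst_size_mean`), for exercising thresholding.
#'
#' @param model a [burst_cycle_model()].
#' @inheritParams simulate_continuous
#' @param output `"binary"` (indicators) or `"counts"`.
#' @param burst_size_mean mean burst size for `output = "counts"`.
#' @return A `pair_obs` tibble, regime `"bursty_binary"` or
#'   `"bursty_count"`.
#' @export
simulate_bursty <- function(model, pairs = NULL, n_obs_per_pair = 1000,
                            seed = NULL, output = c("binary", "counts"),
                            burst_size_mean = 8) {
  stopifnot(inherits(model, "burst_cycle_model"))
  output <- match.arg(output)
  if (n_obs_per_pair < 1L) abort("`n_obs_per_pair` must be at least 1")
  pm <- as_pair_matrix(pairs, model$n_genes)
  fr <- simulate_frame(model$genes, pm, n_obs_per_pair)
  n <- nrow(fr)
  with_seed(seed, {
    tt <- runif(n, 0, model$period)
    g <- if (model$global_noise_sd > 0) {
      sg2 <- model$global_noise_sd^2
      rgamma(n, shape = 1 / sg2, scale = sg2)
    } else {
      rep(1, n)
    }
    pa <- burst_prob_at(model, tt, fr$ia) * g
    pb <- burst_prob_at(model, tt, fr$ib) * g
    xa <- as.numeric(runif(n) < clamp(pa))
    xb <- as.numeric(runif(n) < clamp(pb))
    if (output == "counts") {
      pr <- 1 / burst_size_mean
      xa <- xa * (1 + rgeom(n, pr))
      xb <- xb * (1 + rgeom(n, pr))
    }
    new_pair_obs(
      tibble(
        cell_id = fr$cell_id,
        gene_a = model$genes[fr$ia], gene_b = model$genes[fr$ib],
        count_a = xa, count_b = xb
      ),
      genes = model$genes,
      regime = if (output == "binary") "bursty_binary" else "bursty_count",
      model = model, seed = seed
    )
  })
}

# Unclipped burst probability of gene `idx[k]` at time `tt[k]`.
burst_prob_at <- function(model, tt, idx) {
  p <- model$mean_prob[idx]
  for (h in seq_len(model$n_harmonics)) {
    p <- p + model$amplitude[idx, h] *
      cos(2 * pi * h * tt / model$period + model$phase[idx, h])
  }
  p
}

#' Simulate pairwise snapshots under a stochastic switch
#'
#' Each cell draws one hidden state \eqn{s} with probability \eqn{P_s}
#' (shared by both probed genes); each gene bursts independently with its
#' per-state probability \eqn{q_{i,s}}.
#'
#' @param model a [switch_model()].
#' @inheritParams simulate_continuous
#' @return A `pair_obs` tibble, regime `"bursty_binary"`.
#' @export
simulate_switch <- function(model, pairs = NULL, n_obs_per_pair = 1000,
                            seed = NULL) {
  stopifnot(inherits(model, "switch_model"))
  if (n_obs_per_pair < 1L) abort("`n_obs_per_pair` must be at least 1")
  pm <- as_pair_matrix(pairs, model$n_genes)
  fr <- simulate_frame(model$genes, pm, n_obs_per_pair)
  n <- nrow(fr)
  with_seed(seed, {
    s <- sample.int(model$n_states, n, replace = TRUE, prob = model$state_prob)
    xa <- as.numeric(runif(n) < model$burst_prob[cbind(fr$ia, s)])
    xb <- as.numeric(runif(n) < model$burst_prob[cbind(fr$ib, s)])
    new_pair_obs(
      tibble(
        cell_id = fr$cell_id,
        gene_a = model$genes[fr$ia], gene_b = model$genes[fr$ib],
        count_a = xa, count_b = xb
      ),
      genes = model$genes, regime = "bursty_binary", model = model, seed = seed
    )
  })
}
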