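# Cluster-synchrony statistics for amplitude-locked cyclic fits: the
# mean-normalized cluster activity Q_j(t) and a phase-randomization test
# for its minimum.

normalize_clusters <- function(model, clusters) {
  if (is.data.frame(clusters)) {
    cl <- setNames(as.character(clusters$cluster), clusters$gene)
  } else {
    cl <- setNames(as.character(clusters), names(clusters))
  }
  if (is.null(names(cl))) abort("`clusters` must be named by gene")
  missing <- setdiff(names(cl), model$genes)
  if (length(missing) > 0) {
    abort(paste0("cluster label(s) for unknown gene(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(cl) == 0) abort("`clusters` is empty")
  split(match(names(cl), model$genes), cl)
}

#' Average cluster activity over the cycle
#'
#' For an amplitude-locked cyclic model the mean-normalized burst
#' probability of gene \eqn{i} is \eqn{p_i(t)/\bar p_i =
#' 1 + \cos(2\pi t/T + \phi_i)}, so the activity of cluster \eqn{j} is
#' \deqn{Q_j(t) = \frac{1}{N_j} \sum_{i \in j}
#'   \left[1 + \cos(2\pi t/T + \phi_i)\right].}
#' \eqn{Q_j \ge 0}, its average over a period is exactly 1 for any phases,
#' and its minimum over the cycle is \eqn{1 - R_j/N_j} with
#' \eqn{R_j = |\sum_{i \in j} e^{i\phi_i}|}: a perfectly synchronized
#' cluster reaches 0, while scattered phases keep the minimum near 1.
#' The mean normalization makes clusters with different expression levels
#' comparable at fixed size.
#'
#' @param model an amplitude-locked [burst_cycle_model()].
#' @param clusters gene-to-cluster assignment: a named character vector or
#'   a data frame with columns `gene` and `cluster`.  Every listed gene
#'   must be in the model.
#' @param t_grid evaluation times (default 512 uniform points over one
#'   period).
#' @return A tibble with columns `cluster`, `t`, `activity`.
#' @export
cluster_activity <- function(model, clusters, t_grid = NULL) {
  stopifnot(inherits(model, "burst_cycle_model"))
  if (!model$amplitude_locked) {
    abort("cluster activity is defined for amplitude-locked models")
  }
  groups <- normalize_clusters(model, clusters)
  if (any(lengths(groups) == 0)) abort("empty cluster")
  t_grid <- t_grid %||% (model$period * (seq_len(512) - 1L) / 512)
  purrr::imap(groups, function(idx, name) {
    q <- vapply(t_grid, function(t) {
      mean(1 + cos(2 * pi * t / model$period + model$phase[idx, 1]))
    }, numeric(1))
    tibble(cluster = name, t = t_grid, activity = q)
  }) |>
    bind_rows()
}

#' Minimum cluster activity (exact)
#'
#' Uses the resultant identity \eqn{\min_t Q_j = 1 - R_j/N_j} (see
#' [cluster_activity()]), avoiding any time-grid discretization.
#'
#' @inheritParams cluster_activity
#' @return A tibble with columns `cluster`, `n_genes`, `min_activity`.
#' @export
cluster_min_activity <- function(model, clusters) {
  stopifnot(inherits(model, "burst_cycle_model"))
  if (!model$amplitude_locked) {
    abort("cluster activity is defined for amplitude-locked models")
  }
  groups <- normalize_clusters(model, clusters)
  if (any(lengths(groups) == 0)) abort("empty cluster")
  tibble(
    cluster = names(groups),
    n_genes = unname(lengths(groups)),
    min_activity = unname(vapply(groups, function(idx) {
      1 - Mod(sum(exp(1i * model$phase[idx, 1]))) / length(idx)
    }, numeric(1)))
  )
}

#' Phase-randomization p-value for a cluster-activity minimum
#'
#' Monte-Carlo significance of an observed activity minimum: the fraction
#' of draws of `n_genes` i.i.d. uniform phases whose minimum activity is
#' at most `observed_min`, with the add-one correction
#' \eqn{(k + 1)/(n_{mc} + 1)}.  Low p-values indicate phase synchrony
#' beyond what random phases produce.
#'
#' @param n_genes cluster size (>= 2).
#' @param observed_min observed minimum of the cluster activity.
#' @param n_mc number of Monte-Carlo draws (default `1e5`).
#' @param seed optional seed (the p-value is deterministic given the seed).
#' @return A number in (0, 1].
#' @export
min_activity_pvalue <- function(n_genes, observed_min, n_mc = 1e5,
                                seed = NULL) {
  if (n_genes < 2) abort("`n_genes` must be at least 2")
  with_seed(seed, {
    phi <- matrix(runif(n_mc * n_genes, 0, 2 * pi), n_mc, n_genes)
    r <- Mod(rowSums(exp(1i * phi)))
    null_min <- 1 - r / n_genes
    (sum(null_min <= observed_min) + 1) / (n_mc + 1)
  })
}

#' Synchrony test for all clusters of a fitted cycle
#'
#' Convenience wrapper combining [cluster_min_activity()] and
#' [min_activity_pvalue()] for each cluster.
#'
#' @inheritParams cluster_activity
#' @param n_mc Monte-Carlo draws per cluster.
#' @param seed optional seed.
#' @return A tibble with columns `cluster`, `n_genes`, `min_activity`,
#'   `p_value`.
#' @export
cluster_synchrony_test <- function(model, clusters, n_mc = 1e5,
                                   seed = NULL) {
  mins <- cluster_min_activity(model, clusters)
  mins$p_value <- vapply(seq_len(nrow(mins)), function(k) {
    min_activity_pvalue(
      mins$n_genes[k], mins$min_activity[k], n_mc = n_mc,
      seed = if (is.null(seed)) NULL else seed + k
    )
  }, numeric(1))
  mins
}
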