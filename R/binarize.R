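#' Per-gene binarization thresholds
#'
#' The `"median"` policy sets each gene's threshold to the median of all of
#' its counts pooled across the pairs that probe it, using the lower median
#' for even sample sizes (so thresholds are always observed integer
#' counts).  A burst is subsequently defined as a count *strictly* above
#' the threshold, which makes the median a robust choice: in strongly
#' bursty data most medians are zero.
#'
#' @param data a `pair_obs` tibble (count regime).
#' @param policy `"median"` or `"fixed"`.
#' @param thresholds named numeric vector of user thresholds (required for
#'   `policy = "fixed"`).
#' @return Named integer-valued vector of thresholds, one per gene.
#' @export
compute_thresholds <- function(data, policy = c("median", "fixed"),
                               thresholds = NULL) {
  policy <- match.arg(policy)
  genes <- pair_obs_genes(data)
  if (policy == "fixed") {
    if (is.null(thresholds)) abort("`thresholds` is required for policy = \"fixed\"")
    if (is.null(names(thresholds))) names(thresholds) <- genes
    missing <- setdiff(genes, names(thresholds))
    if (length(missing) > 0) {
      abort(paste0("no threshold supplied for gene(s): ",
                   paste(missing, collapse = ", ")))
    }
    return(thresholds[genes])
  }
  pooled <- pooled_counts(data, genes)
  out <- vapply(genes, function(g) {
    x <- pooled[[g]]
    if (length(x) == 0) {
      abort(paste0("gene has no observations: ", g))
    }
    lower_median(x)
  }, numeric(1))
  out
}

# Lower median: the floor((n+1)/2)-th order statistic.
lower_median <- function(x) {
  sort(x)[(length(x) + 1L) %/% 2L]
}

pooled_counts <- function(data, genes) {
  out <- lapply(genes, function(g) {
    c(data$count_a[data$gene_a == g], data$count_b[data$gene_b == g])
  })
  names(out) <- genes
  out
}

#' Threshold counts into burst indicators
#'
#' Sets the indicator to 1 exactly when the count is strictly larger than
#' the gene's threshold.  Idempotent on already-binary data with threshold
#' zero.
#'
#' @param data a `pair_obs` tibble.
#' @param thresholds named vector of per-gene thresholds (e.g. from
#'   [compute_thresholds()]).
#' @return A `pair_obs` tibble with regime `"bursty_binary"`; the
#'   thresholds used are attached as attribute `"thresholds"`.
#' @export
binarize <- function(data, thresholds) {
  genes <- pair_obs_genes(data)
  if (is.null(names(thresholds))) {
    if (length(thresholds) != length(genes)) {
      abort("`thresholds` must have one entry per gene")
    }
    names(thresholds) <- genes
  }
  missing <- setdiff(genes, names(thresholds))
  if (length(missing) > 0) {
    abort(paste0("no threshold for gene(s): ", paste(missing, collapse = ", ")))
  }
  out <- mutate(
    as_tibble(data),
    count_a = as.numeric(.data$count_a > thresholds[.data$gene_a]),
    count_b = as.numeric(.data$count_b > thresholds[.data$gene_b])
  )
  out <- new_pair_obs(out, genes = genes, regime = "bursty_binary",
                      model = pair_obs_model(data), seed = attr(data, "seed"))
  attr(out, "thresholds") <- thresholds[genes]
  out
}

#' Sampling variance of a pairwise covariance estimate
#'
#' For a pair observed in `n_obs` cells with coincidence frequency
#' \eqn{\hat r} (the fraction of cells where both indicators are 1), the
#' leading-order sampling variance of the covariance estimate is the
#' Bernoulli coincidence variance \eqn{\hat r(1 - \hat r)/M}.  Pairs with
#' no observed coincidences would get zero variance and an infinite
#' likelihood weight, so the variance is floored at
#' \eqn{\varepsilon / M^2} -- the value corresponding to a fraction
#' \eqn{\varepsilon} of a single coincident count.
#'
#' @param r_hat coincidence frequency (vectorized).
#' @param n_obs number of observations for the pair (>= 2).
#' @param eps variance floor, in units of one squared count
#'   (default 0.25).
#' @return A tibble with columns `c_var` and `var_floored`.
#' @export
#' @examples
#' estimate_cov_variance(0.5, 100)  # 0.25 / 100
#' estimate_cov_variance(0, 100)    # floored at 0.25 / 100^2
estimate_cov_variance <- function(r_hat, n_obs, eps = 0.25) {
  if (any(n_obs < 2)) abort("`n_obs` must be at least 2")
  raw <- r_hat * (1 - r_hat) / n_obs
  floor_val <- eps / n_obs^2
  tibble(
    c_var = pmax(raw, floor_val),
    var_floored = raw < floor_val
  )
}

#' Estimate measurable moments from binarized pair data
#'
#' Computes the pooled per-gene burst frequencies \eqn{\hat p_i} (each gene
#' pooled over every pair that probes it) and, per pair, the covariance
#' estimate \eqn{\hat c_{ij} = \hat r_{ij} - \hat p_i^{(ij)}
#' \hat p_j^{(ij)}} built from the within-pair means, together with its
#' sampling variance from [estimate_cov_variance()].  The diagonal
#' \eqn{c_{ii}} is not measurable from pairwise snapshot data and is not
#' reported.
#'
#' @param data a `pair_obs` tibble with regime `"bursty_binary"`.
#' @param eps variance floor passed to [estimate_cov_variance()].
#' @return An object of class `moment_estimates`: a list with
#'   * `genes`: tibble `gene`, `n_obs`, `p_hat`, `threshold`;
#'   * `pairs`: tibble `gene_a`, `gene_b`, `n_obs`, `r_hat`, `c_hat`,
#'     `c_var`, `var_floored`.
#' @export
estimate_moments <- function(data, eps = 0.25) {
  if (!identical(pair_obs_regime(data), "bursty_binary")) {
    abort("`data` must be binarized first (regime \"bursty_binary\")")
  }
  vals <- c(data$count_a, data$count_b)
  if (!all(vals %in% c(0, 1))) abort("binary data must contain only 0/1 indicators")
  genes <- pair_obs_genes(data)
  thresholds <- attr(data, "thresholds")

  pooled <- pooled_counts(data, genes)
  gene_tbl <- tibble(
    gene = genes,
    n_obs = unname(vapply(pooled, length, integer(1))),
    p_hat = unname(vapply(pooled, function(x) if (length(x)) mean(x) else NA_real_,
                          numeric(1))),
    threshold = if (is.null(thresholds)) NA_real_ else as.numeric(thresholds[genes])
  )
  if (any(gene_tbl$n_obs == 0)) {
    abort(paste0("gene(s) with no observations: ",
                 paste(genes[gene_tbl$n_obs == 0], collapse = ", ")))
  }

  pair_tbl <- as_tibble(data) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(
      n_obs = dplyr::n(),
      r_hat = mean(.data$count_a * .data$count_b),
      c_hat = mean(.data$count_a * .data$count_b) -
        mean(.data$count_a) * mean(.data$count_b),
      .groups = "drop"
    )
  vv <- estimate_cov_variance(pair_tbl$r_hat, pair_tbl$n_obs, eps = eps)
  pair_tbl$c_var <- vv$c_var
  pair_tbl$var_floored <- vv$var_floored

  structure(
    list(genes = gene_tbl, pairs = pair_tbl),
    class = "moment_estimates"
  )
}

#' @export
print.moment_estimates <- function(x, ...) {
  cat(sprintf(
    "<moment_estimates> %d genes, %d pairs (observations per pair %d-%d)\n",
    nrow(x$genes), nrow(x$pairs), min(x$pairs$n_obs), max(x$pairs$n_obs)
  ))
  cat("per-gene burst frequencies:\n")
  print(x$genes, ...)
  cat("pairwise covariance estimates:\n")
  print(x$pairs, ...)
  invisible(x)
}

#' @rdname estimate_moments
#' @param x a `moment_estimates` object.
#' @param ... unused.
#' @export
tidy.moment_estimates <- function(x, ...) x$pairs

#' @rdname estimate_moments
#' @export
glance.moment_estimates <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes), n_pairs = nrow(x$pairs),
    n_obs_total = sum(x$pairs$n_obs),
    min_pair_obs = min(x$pairs$n_obs), max_pair_obs = max(x$pairs$n_obs),
    n_var_floored = sum(x$pairs$var_floored)
  )
}

# Gene-index lookup and theory-covariance extraction used by the bursty
# fitters: moments estimates index pairs by gene name.
moment_pair_index <- function(est, genes) {
  ia <- match(est$pairs$gene_a, genes)
  ib <- match(est$pairs$gene_b, genes)
  if (anyNA(ia) || anyNA(ib)) abort("pair table contains unknown genes")
  cbind(ia, ib)
}
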