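# Shared helpers: hand-built observation sets and block-based Monte-Carlo
# standard errors for oracle comparisons.

# Build a pair_obs tibble directly from per-pair count vectors.
# `pairs` is a list of lists with fields gene_a, gene_b, count_a, count_b.
make_pair_obs <- function(pairs, genes = NULL, regime = "bursty_binary") {
  df <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(
      gene_a = p$gene_a, gene_b = p$gene_b,
      count_a = p$count_a, count_b = p$count_b
    )
  }))
  df <- dplyr::mutate(df, cell_id = dplyr::row_number(), .before = 1)
  if (is.null(genes)) genes <- unique(c(df$gene_a, df$gene_b))
  snapdyn:::new_pair_obs(df, genes = genes, regime = regime)
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

# Mean and standard error of a statistic computed over blocks of a vector.
block_se <- function(x, n_blocks = 10) {
  f <- rep(seq_len(n_blocks), length.out = length(x))
  m <- tapply(x, f, mean)
  list(mean = mean(m), se = stats::sd(m) / sqrt(n_blocks))
}

# Sample covariance of two vectors with a block-based standard error.
block_cov_se <- function(x, y, n_blocks = 10) {
  f <- rep(seq_len(n_blocks), length.out = length(x))
  cc <- vapply(split(seq_along(x), f), function(i) {
    mean(x[i] * y[i]) - mean(x[i]) * mean(y[i])
  }, numeric(1))
  list(mean = mean(cc), se = stats::sd(cc) / sqrt(n_blocks))
}

expect_within_3se <- function(observed_mean, se, expected) {
  expect_lt(abs(observed_mean - expected), 3 * se + 1e-12)
}
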