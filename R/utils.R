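# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

wrap_phase <- function(phi) {
  out <- phi %% (2 * pi)
  out
}

is_symmetric_tol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m)), na.rm = TRUE) <= tol * max(1, max(abs(m), na.rm = TRUE))
}

default_gene_names <- function(n) sprintf("g%02d", seq_len(n))

# All unordered index pairs (i < j) as a 2-column integer matrix.
all_pairs <- function(n_genes) {
  t(combn(n_genes, 2L))
}

# Normalise a `pairs` argument (NULL, 2-column matrix, or data frame with
# integer columns) to a 2-column integer matrix with i != j.
as_pair_matrix <- function(pairs, n_genes) {
  if (is.null(pairs)) {
    return(all_pairs(n_genes))
  }
  pm <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pm) <- "integer"
  if (any(pm[, 1] == pm[, 2])) {
    abort("each pair must involve two distinct genes")
  }
  if (any(pm < 1L) || any(pm > n_genes)) {
    abort("pair indices out of range")
  }
  pm
}

# Simple permutation enumeration for small n (used for switch-state
# relabeling); returns a list of integer vectors.
permutations <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations(n - 1L)
    idx <- setdiff(seq_len(n), i)
    out <- c(out, lapply(rest, function(p) c(i, idx[p])))
  }
  out
}
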