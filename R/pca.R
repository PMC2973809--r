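# PCA of the estimated between-gene covariance.  The diagonal (per-gene
# indicator variance over the hidden cycle/states) is not measurable from
# pairwise snapshot data, so it is completed iteratively from a low-rank
# reconstruction.

#' Assemble the estimated covariance matrix from moment estimates
#'
#' Builds the symmetric between-gene covariance matrix from the pairwise
#' estimates, with `NA` on the diagonal (unobservable) and on pairs that
#' were never measured.
#'
#' @param est a `moment_estimates` object.
#' @return A symmetric matrix with gene dimnames.
#' @export
moment_cov_matrix <- function(est) {
  genes <- est$genes$gene
  n <- length(genes)
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  idx <- moment_pair_index(est, genes)
  m[idx] <- est$pairs$c_hat
  m[idx[, 2:1, drop = FALSE]] <- est$pairs$c_hat
  m
}

#' PCA with iterative completion of the missing diagonal
#'
#' Starting from the estimated covariance with a zero diagonal, repeatedly
#' (1) eigendecompose, (2) keep the top-`rank` eigenpairs, (3) replace the
#' diagonal by the diagonal of the rank-`rank` reconstruction, until the
#' largest diagonal change falls below `tol`.  Off-diagonal entries are
#' never modified.  Unmeasured off-diagonal pairs are imputed as 0
#' (unbiased under no signal) and counted in `n_imputed`.
#'
#' @param c_hat symmetric matrix with missing (`NA`) diagonal, e.g. from
#'   [moment_cov_matrix()], or a `moment_estimates` object.
#' @param rank target rank of the reconstruction.
#' @param tol convergence tolerance on the diagonal update
#'   (default `1e-10`).
#' @param max_iter maximum number of iterations (default 500).
#' @return An object of class `pca_completion`: list with
#'   `completed_cov`, `eigenvalues` (descending), `eigenvectors`
#'   (orthonormal columns), `n_iterations`, `converged`, `final_delta`,
#'   `inferred_rank` (from [infer_complexity()]), `n_imputed`.
#' @export
pca_complete <- function(c_hat, rank = 1, tol = 1e-10, max_iter = 500) {
  if (inherits(c_hat, "moment_estimates")) c_hat <- moment_cov_matrix(c_hat)
  if (!is.matrix(c_hat) || nrow(c_hat) != ncol(c_hat)) {
    abort("`c_hat` must be a square matrix")
  }
  off <- c_hat
  diag(off) <- 0
  n_imputed <- sum(is.na(off)) / 2
  off[is.na(off)] <- 0
  if (!is_symmetric_tol(off)) abort("`c_hat` must be symmetric")
  m <- off  # zero diagonal start
  converged <- FALSE
  delta <- Inf
  iter <- 0L
  es <- eigen(m, symmetric = TRUE)
  for (iter in seq_len(max_iter)) {
    es <- eigen(m, symmetric = TRUE)
    keep <- seq_len(min(rank, ncol(m)))
    v <- es$vectors[, keep, drop = FALSE]
    lam <- es$values[keep]
    new_diag <- rowSums((v^2) %*% diag(lam, nrow = length(lam)))
    delta <- max(abs(new_diag - diag(m)))
    diag(m) <- new_diag
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  es <- eigen(m, symmetric = TRUE)
  cmplx <- infer_complexity(es$values)
  structure(
    list(
      completed_cov = m,
      eigenvalues = es$values,
      eigenvectors = es$vectors,
      n_iterations = iter,
      converged = converged,
      final_delta = delta,
      inferred_rank = cmplx$rank,
      n_imputed = n_imputed,
      rank = rank
    ),
    class = "pca_completion"
  )
}

#' @export
print.pca_completion <- function(x, ...) {
  cat(sprintf(
    "<pca_completion> rank-%d completion of a %dx%d covariance (%s in %d iterations)\n",
    x$rank, nrow(x$completed_cov), ncol(x$completed_cov),
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  cat("leading eigenvalues:\n")
  print(signif(head(x$eigenvalues, 6), 4))
  cat(sprintf("inferred rank: %d\n", x$inferred_rank))
  invisible(x)
}

#' Infer dynamical complexity from the eigenvalue spectrum
#'
#' Isolates the group of eigenvalues significantly larger than the rest:
#' the inferred rank is the number of eigenvalues above
#' `noise_factor` times the median absolute eigenvalue.  The rank maps to
#' candidate model families (with the ambiguities intrinsic to pairwise
#' data): rank 1 suggests a 2-state switch; rank 2 a single-harmonic
#' cycle or a 3-state switch; rank 3 a cycle with global noise or a
#' 4-state switch.  Prior knowledge must select among the candidates.
#'
#' The median-based threshold presumes the signal rank is well below the
#' number of genes (the regime pairwise studies target); a relative floor
#' of `rel_floor` times the largest eigenvalue magnitude guards against
#' counting numerical zeros when the spectrum is exact.
#'
#' @param eigenvalues numeric vector, sorted descending.
#' @param noise_factor threshold multiplier on the median absolute
#'   eigenvalue (default 5).
#' @param rel_floor relative numerical-zero floor (default `1e-8`).
#' @return A list with `rank`, `threshold`, and `suggested_models`
#'   (character vector).
#' @export
infer_complexity <- function(eigenvalues, noise_factor = 5,
                             rel_floor = 1e-8) {
  if (is.unsorted(rev(eigenvalues))) {
    abort("`eigenvalues` must be sorted in descending order")
  }
  threshold <- max(noise_factor * median(abs(eigenvalues)),
                   rel_floor * max(abs(eigenvalues), 0))
  rank <- sum(eigenvalues > threshold)
  suggested <- switch(as.character(rank),
    "0" = "no dynamical signal",
    "1" = "2-state switch",
    "2" = c("1-harmonic cycle", "3-state switch"),
    "3" = c("1-harmonic cycle + global noise", "4-state switch"),
    c(
      sprintf("%d-harmonic cycle", ceiling(rank / 2)),
      sprintf("%d-state switch", rank + 1L)
    )
  )
  list(rank = as.integer(rank), threshold = threshold,
       suggested_models = suggested)
}

#' Extract a two-state switch model from a PCA completion
#'
#' For a 2-state switch the exact covariance is
#' \eqn{c = P_1(1-P_1)\,\delta\delta^\top} with
#' \eqn{\delta = q_{\cdot,1} - q_{\cdot,2}}, so the principal eigenvector
#' of the completed covariance directly yields the difference of burst
#' probabilities: \eqn{\delta = v_1 \sqrt{\lambda_1 / (P_1(1-P_1))}} up to
#' sign.  Combined with the measured means this gives
#' \eqn{q_{i,1} = \hat p_i + (1-P_1)\delta_i},
#' \eqn{q_{i,2} = \hat p_i - P_1 \delta_i}; the sign is chosen so state 1
#' has the larger mean burst probability, and any values outside
#' \eqn{[0,1]} are clipped (the clipped fraction is reported as attribute
#' `"clip_fraction"`).
#'
#' @param pca a `pca_completion` (rank 1).
#' @param p_hat measured mean burst probabilities (named or in gene order).
#' @param p1 known probability of state 1, in (0, 1).
#' @return A [switch_model()] with attribute `clip_fraction`.
#' @export
switch_from_pca <- function(pca, p_hat, p1) {
  stopifnot(inherits(pca, "pca_completion"))
  if (p1 <= 0 || p1 >= 1) abort("`p1` must lie strictly between 0 and 1")
  lam <- pca$eigenvalues[1]
  if (lam <= 0) abort("leading eigenvalue is not positive: no switch signal")
  genes <- rownames(pca$completed_cov) %||% default_gene_names(length(p_hat))
  delta <- pca$eigenvectors[, 1] * sqrt(lam / (p1 * (1 - p1)))
  q1 <- p_hat + (1 - p1) * delta
  q2 <- p_hat - p1 * delta
  if (mean(q1) < mean(q2)) {
    delta <- -delta
    q1 <- p_hat + (1 - p1) * delta
    q2 <- p_hat - p1 * delta
  }
  clip_fraction <- mean(c(q1, q2) < 0 | c(q1, q2) > 1)
  out <- switch_model(c(p1, 1 - p1), cbind(clamp(q1), clamp(q2)),
                      genes = genes)
  attr(out, "clip_fraction") <- clip_fraction
  out
}
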