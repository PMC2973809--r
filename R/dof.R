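#' Identifiability accounting for bursty-regime models
#'
#' Counts model parameters, the constraints supplied by pairwise snapshot
#' data (per-gene means plus a rank-limited symmetric covariance), and the
#' number of parameters left unconstrained -- i.e. how many additional
#' constraints (for instance triplet measurements) are needed for complete
#' inference.
#'
#' For a cyclic burst-probability model with \eqn{H} harmonics and
#' \eqn{N} genes the parameter count is \eqn{N(1 + 2H) - 1}: mean, and one
#' amplitude and phase per harmonic per gene, minus one for the invariance
#' under a global phase shift.  The covariance matrix has rank
#' \eqn{r = 2H}, so (for large enough \eqn{N}) it supplies
#' \eqn{rN - r(r-1)/2} constraints; in general the count is capped at the
#' \eqn{N(N-1)/2} observable off-diagonal entries.  For an \eqn{S}-state
#' switch the parameter count is \eqn{(S-1) + SN} and the covariance rank
#' is \eqn{S - 1}.  Fitting a global-noise amplitude adds one parameter and
#' raises the covariance rank by one.
#'
#' @param family `"cycle"` or `"switch"`.
#' @param n_genes number of genes \eqn{N \ge 2}.
#' @param n_harmonics number of harmonics (cycle family).
#' @param n_states number of states (switch family).
#' @param global_noise whether a global transcriptional noise amplitude is
#'   part of the model.
#' @return A one-row tibble of class `dof_report` with columns
#'   `model_family`, `n_genes`, `n_harmonics`, `n_states`, `n_parameters`,
#'   `n_constraints`, `n_unconstrained`, `cov_rank`, and `capped`
#'   (`TRUE` when the covariance constraint count was limited by the number
#'   of observable pairs rather than by the rank).
#' @export
#' @examples
#' dof_report("cycle", n_genes = 25, n_harmonics = 1)  # 74 parameters
#' dof_report("switch", n_genes = 6, n_states = 2)     # 1 unconstrained
dof_report <- function(family = c("cycle", "switch"), n_genes,
                       n_harmonics = NULL, n_states = NULL,
                       global_noise = FALSE) {
  family <- match.arg(family)
  if (n_genes < 2L) abort("`n_genes` must be at least 2")
  extra <- as.integer(isTRUE(global_noise))
  if (family == "cycle") {
    if (is.null(n_harmonics) || n_harmonics < 1L) {
      abort("`n_harmonics` must be at least 1 for the cycle family")
    }
    n_par <- n_genes * (1L + 2L * n_harmonics) - 1L + extra
    r <- 2L * n_harmonics + extra
  } else {
    if (is.null(n_states) || n_states < 2L) {
      abort("`n_states` must be at least 2 for the switch family")
    }
    n_par <- (n_states - 1L) + n_states * n_genes + extra
    r <- n_states - 1L + extra
  }
  from_rank <- r * n_genes - (r * (r - 1L)) %/% 2L
  n_offdiag <- (n_genes * (n_genes - 1L)) %/% 2L
  capped <- from_rank > n_offdiag
  cov_constraints <- min(from_rank, n_offdiag)
  n_constraints <- n_genes + cov_constraints
  out <- tibble(
    model_family = family,
    n_genes = as.integer(n_genes),
    n_harmonics = if (family == "cycle") as.integer(n_harmonics) else NA_integer_,
    n_states = if (family == "switch") as.integer(n_states) else NA_integer_,
    n_parameters = as.integer(n_par),
    n_constraints = as.integer(n_constraints),
    n_unconstrained = as.integer(max(0L, n_par - n_constraints)),
    cov_rank = as.integer(r),
    capped = capped
  )
  class(out) <- c("dof_report", class(out))
  out
}
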