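#' Reference solvers: three representations of the same master equation
#'
#' The package solves one master equation in three state representations,
#' mirrored after benchmark comparisons of such solvers: `"full"` (all
#' spin-1/2 nuclei explicit, no symmetry used; the validation oracle),
#' `"k_reduced"` (effective spins for equivalent groups, full Liouville
#' space otherwise) and `"zqc"` (effective spins plus restriction to the
#' zero-quantum-coherence subspace; the production path). All three share
#' the operator, relaxation and exchange builders, so comparisons isolate
#' the reduction logic.
#'
#' @param model A `sabre_model`.
#' @param b0_t Polarization field (tesla).
#' @param tpol Polarization time (s).
#' @param tol Propagation tolerance.
#' @param full_cap Refusal threshold on the full Liouville dimension.
#' @return Tibble with `nucleus`, `polarization` (weight-averaged over
#'   configurations where applicable).
#' @export
solve_full <- function(model, b0_t, tpol, tol = 1e-9, full_cap = 1e6) {
  res <- field_scan(model, b0_t, tpol, representation = "full",
                    tol = tol, full_cap = full_cap)
  average_configs(res, check_weights = FALSE)[, c("nucleus", "polarization")]
}

#' @rdname solve_full
#' @export
solve_k_reduced <- function(model, b0_t, tpol, tol = 1e-9) {
  res <- field_scan(model, b0_t, tpol, representation = "k_reduced", tol = tol)
  average_configs(res)[, c("nucleus", "polarization")]
}

#' @rdname solve_full
#' @export
solve_zqc <- function(model, b0_t, tpol, tol = 1e-9) {
  res <- field_scan(model, b0_t, tpol, representation = "zqc", tol = tol)
  average_configs(res)[, c("nucleus", "polarization")]
}

# dense complex matrix exponential (eigendecomposition with a Taylor
# scaling fallback); independent oracle for small-system tests
expm_dense <- function(M, t) {
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  if (!is.null(eg) && is.finite(rcond_est <- tryCatch(
    1 / kappa(eg$vectors), error = function(e) 0)) && rcond_est > 1e-10) {
    V <- eg$vectors
    return(V %*% diag(exp(eg$values * t), nrow(M)) %*% solve(V))
  }
  # scaling and squaring with a plain Taylor series
  n <- nrow(M)
  nrm <- max(rowSums(abs(M))) * abs(t)
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))))
  A <- M * (t / 2^s)
  E <- diag(1 + 0i, n)
  term <- diag(1 + 0i, n)
  for (k in 1:60) {
    term <- term %*% A / k
    E <- E + term
    if (max(Mod(term)) < 1e-18) break
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}
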