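#' Relaxation specification for a configured spin system
#'
#' Random-fluctuating-field (RFF) Redfield relaxation in the extreme-
#' narrowing limit. By default each site of the reduced system relaxes
#' independently with its own `T1` (an effective spin K carries the group's
#' shared `T1`, giving the collective group term); a full correlation
#' matrix over sites can be supplied for the general form with cross terms
#' `-(1/2) C_nl / sqrt(T1_n T1_l)`.
#'
#' @param config An `effective_config` or reduced `spin_system`.
#' @param t1 Optional named numeric vector overriding the per-site T1 (s);
#'   `NA` omits a site's relaxation entirely.
#' @param correlation Optional symmetric site-correlation matrix with unit
#'   diagonal and entries in `[0, 1]`; default is the identity (effective
#'   spins already encode full within-group correlation).
#' @return Object of class `relaxation_spec`.
#' @export
relaxation_spec <- function(config, t1 = NULL, correlation = NULL) {
  system <- as_reduced_system(config)
  labels <- system$nuclei$label
  t1v <- stats::setNames(system$nuclei$t1, labels)
  if (!is.null(t1)) t1v[names(t1)] <- t1
  if (any(!is.na(t1v) & t1v <= 0)) stop("T1 must be positive", call. = FALSE)
  n <- length(labels)
  C <- if (is.null(correlation)) diag(1, n, n) else as.matrix(correlation)
  if (!isTRUE(all.equal(C, t(C))) || any(diag(C) != 1) ||
      any(C < 0) || any(C > 1)) {
    stop("correlation matrix must be symmetric with unit diagonal and ",
         "entries in [0, 1]", call. = FALSE)
  }
  structure(list(t1 = t1v, correlation = C, labels = labels),
            class = "relaxation_spec")
}

#' RFF Redfield relaxation superoperator
#'
#' Builds `G = -(1/2) sum_{n,l} C_nl / sqrt(T1_n T1_l) sum_m (-1)^m
#' Tsup(1,-m; n) Tsup(1,m; l)` on the full Liouville space of the reduced
#' system, where `Tsup` are commutation superoperators of the embedded
#' rank-1 spherical tensors (spin-1/2 or spin-K as appropriate). With the
#' default diagonal correlation this is the sum of independent single-site
#' terms at rates `1/T1_n` plus one collective term per effective spin at
#' rate `1/T1_P`. The result is real, trace preserving, commutes with the
#' total-Fz superoperator, and gives `T2 = T1` per site (isotropic local
#' fields, extreme narrowing).
#'
#' @param config An `effective_config` or reduced `spin_system`.
#' @param spec Optional [relaxation_spec()]; built from the system's `t1`
#'   column when omitted.
#' @return A `superop` on the `d^2`-dimensional Liouville space.
#' @export
build_relaxation_superoperator <- function(config, spec = NULL) {
  basis <- labeled_basis(config)
  spec <- spec %||% relaxation_spec(config)
  d2 <- basis$d^2
  acc <- NULL
  terms <- relaxation_site_pairs(spec)
  for (tr in terms) {
    n <- tr$n; l <- tr$l; c_nl <- tr$rate
    for (m in c(-1L, 0L, 1L)) {
      Sn <- commutation_superoperator(embedded_tensor(basis, n, -m))$re
      Sl <- commutation_superoperator(embedded_tensor(basis, l, m))$re
      term <- (-0.5) * c_nl * (-1)^m * (Sn %*% Sl)
      acc <- if (is.null(acc)) term else acc + term
    }
  }
  if (is.null(acc)) return(sop_zero(d2))
  superop(acc)
}

# ZQC-projected relaxation superoperator, assembled without materializing
# the parent Liouville operator: each tensor superoperator is restricted to
# act between the q = 0 and q = m coherence-order subspaces.
build_relaxation_zqc <- function(basis, spec) {
  zn <- attr(subspace_blocks(basis, 0L), "total")
  acc <- NULL
  terms <- relaxation_site_pairs(spec)
  for (tr in terms) {
    for (m in c(-1L, 0L, 1L)) {
      m2 <- 2L * m
      Tl <- embedded_tensor(basis, tr$l, m)
      Tn <- embedded_tensor(basis, tr$n, -m)
      up <- commutation_shift_matrix(Tl, m2, basis, 0L)
      down <- commutation_shift_matrix(Tn, -m2, basis, m2)
      term <- (-0.5) * tr$rate * (-1)^m * (down %*% up)
      acc <- if (is.null(acc)) term else acc + term
    }
  }
  if (is.null(acc)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(zn, zn)))
  }
  methods::as(acc, "CsparseMatrix")
}

# site pairs (n, l) with nonzero rate C_nl / sqrt(T1_n T1_l); sites with
# unset T1 are omitted rather than treated as T1 = Inf
relaxation_site_pairs <- function(spec) {
  t1 <- spec$t1
  C <- spec$correlation
  n_sites <- length(t1)
  out <- list()
  for (n in seq_len(n_sites)) {
    for (l in seq_len(n_sites)) {
      if (is.na(t1[n]) || is.na(t1[l])) next
      if (C[n, l] == 0) next
      out[[length(out) + 1L]] <-
        list(n = n, l = l, rate = C[n, l] / sqrt(t1[n] * t1[l]))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
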