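#' Piecewise-constant magnetic-field protocol
#'
#' The low-field Hamiltonian is time dependent only through `B0(t)`;
#' protocols are represented as piecewise-constant segments, which is also
#' how ramps are discretized.
#'
#' @param b0_t Numeric vector of field values (tesla; 0 allowed).
#' @param duration_s Numeric vector of positive segment durations (s).
#' @return Tibble of class `field_protocol` with columns `b0_t`, `duration_s`.
#' @export
field_protocol <- function(b0_t, duration_s) {
  if (length(b0_t) != length(duration_s)) {
    stop("b0_t and duration_s must have the same length", call. = FALSE)
  }
  if (any(!is.finite(b0_t))) stop("fields must be finite", call. = FALSE)
  if (any(duration_s <= 0)) stop("durations must be positive", call. = FALSE)
  structure(tibble::tibble(b0_t = b0_t, duration_s = duration_s),
            class = c("field_protocol", "tbl_df", "tbl", "data.frame"))
}

#' @rdname field_protocol
#' @param duration_s Total duration (s).
#' @export
constant_field <- function(b0_t, duration_s) field_protocol(b0_t, duration_s)

#' @rdname field_protocol
#' @param from,to Endpoint fields (tesla) of a linear ramp.
#' @param n_steps Number of piecewise-constant steps the ramp is cut into
#'   (midpoint values).
#' @export
field_ramp <- function(from, to, duration_s, n_steps = 50) {
  edges <- seq(from, to, length.out = n_steps + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  field_protocol(mid, rep(duration_s / n_steps, n_steps))
}

#' Low-field Hamiltonian of a configured spin system
#'
#' `H = -B0 * sum_l gamma_l (1 + delta_l*1e-6) Iz_l
#'      + 2*pi * sum_{l<m} J_lm (I_l . I_m)` in rad/s, built on the reduced
#' system of an effective-spin configuration. Couplings internal to an
#' equivalence group were removed by the reduction (they do not affect the
#' dynamics within a K block); couplings between groups and to external
#' nuclei use the common group values. The result is a real sparse matrix,
#' Hermitian, commuting with total Fz.
#'
#' @param config An `effective_config` (or group-free `spin_system`).
#' @param b0_t Magnetic field in tesla.
#' @return Real sparse Hamiltonian matrix (rad/s).
#' @export
build_hamiltonian <- function(config, b0_t) {
  p <- hamiltonian_parts(config)
  methods::as(p$h_j + b0_t * p$h_z, "CsparseMatrix")
}

# field-independent J part and per-tesla Zeeman part; field scans combine
# them linearly instead of rebuilding operators
hamiltonian_parts <- function(config) {
  system <- as_reduced_system(config)
  dims <- system_dims(system)
  spins <- system_spins(system)
  n <- length(dims)
  gam_eff <- system$nuclei$gamma * (1 + system$shifts_ppm[system$nuclei$label] * 1e-6)
  # Zeeman: diagonal with per-state sum of gamma*m
  zdiag <- 0
  for (i in seq_len(n)) {
    m_i <- spins[i] - (seq_len(dims[i]) - 1)
    d_right <- prod(dims[-seq_len(i)])
    d_left <- prod(dims[seq_len(i - 1)])
    zdiag <- zdiag + gam_eff[i] * rep(rep(m_i, each = d_right), times = d_left)
  }
  h_z <- -Matrix::Diagonal(x = zdiag)
  h_j <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(prod(dims), prod(dims)))
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        Jab <- system$j[a, b]
        if (Jab != 0) {
          h_j <- h_j + (2 * pi * Jab) * scalar_coupling_operator(a, b, dims, spins)
        }
      }
    }
  }
  list(h_j = methods::as(h_j, "CsparseMatrix"),
       h_z = methods::as(h_z, "CsparseMatrix"),
       dims = dims, spins = spins, labels = system$nuclei$label)
}

#' Commutation superoperator of a Hilbert-space operator
#'
#' Maps `A` to the Liouville superoperator `A (x) 1 - 1 (x) t(A)` acting on
#' row-major vectorized operators: `S vec(X) = vec(A X - X A)`. The row-major
#' convention (`|r><c|` at index `(r-1)*d + c`) makes the Kronecker formula
#' literal.
#'
#' @param A Square matrix (real or complex; sparse or dense).
#' @return A `superop`.
#' @export
commutation_superoperator <- function(A) {
  if (nrow(A) != ncol(A)) stop("operator must be square", call. = FALSE)
  if (is.complex(A)) {
    re <- build_comm(Re(A))
    im_part <- Im(A)
    im <- if (any(im_part != 0)) build_comm(im_part) else NULL
    superop(re, im)
  } else {
    superop(build_comm(A))
  }
}

build_comm <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  d <- nrow(A)
  Matrix::kronecker(A, Matrix::Diagonal(d)) -
    Matrix::kronecker(Matrix::Diagonal(d), Matrix::t(A))
}
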