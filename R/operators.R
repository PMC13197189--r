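#' Angular-momentum matrices for an arbitrary spin
#'
#' Standard spin matrices in the descending-m basis (m = +s first). The
#' convention fixes deterministic indices for every composite operator in the
#' package: the z projection of a product state is then the plain sum of the
#' per-site m values read off the basis index.
#'
#' @param s Spin quantum number (half-integer, >= 1/2 for physical nuclei;
#'   0 is permitted and yields 1x1 matrices so spin-0 effective groups embed
#'   trivially).
#' @return List with elements `Ix`, `Iy`, `Iz`, `Iplus`, `Iminus`,
#'   `identity`; all `(2s+1) x (2s+1)` matrices. `Iy` is complex, all others
#'   real.
#' @examples
#' spin_matrices(1/2)$Iz        # diag(1/2, -1/2)
#' spin_matrices(3/2)$Iz        # diag(3/2, 1/2, -1/2, -3/2)
#' @export
spin_matrices <- function(s) {
  if (length(s) != 1L || !is.finite(s) || s < 0 || !is_half_integer(s)) {
    stop("spin must be a non-negative half-integer, got ", s, call. = FALSE)
  }
  n <- as.integer(round(2 * s + 1))
  m <- s - (seq_len(n) - 1)          # descending: +s, s-1, ..., -s
  Iz <- diag(m, n, n)
  # raising operator in descending-m basis: |m+1><m| sits above the diagonal
  Iplus <- matrix(0, n, n)
  if (n > 1) {
    lad <- sqrt(s * (s + 1) - m[-1] * (m[-1] + 1))
    Iplus[cbind(seq_len(n - 1), 2:n)] <- lad
  }
  Iminus <- t(Iplus)
  list(
    Ix = (Iplus + Iminus) / 2,
    Iy = (Iplus - Iminus) / (2i),
    Iz = Iz,
    Iplus = Iplus,
    Iminus = Iminus,
    identity = diag(1, n, n)
  )
}

#' Rank-1 irreducible spherical tensor operator for a spin
#'
#' `T(1,+1) = -(Ix + iIy)/sqrt(2)`, `T(1,0) = Iz`,
#' `T(1,-1) = (Ix - iIy)/sqrt(2)`. The same construction serves spin-1/2
#' nuclei and effective spins K. All three components are real matrices in
#' the descending-m basis.
#'
#' @param s Spin quantum number.
#' @param m Tensor component, one of -1, 0, +1.
#' @return Real `(2s+1) x (2s+1)` matrix.
#' @export
spherical_tensor <- function(s, m) {
  if (!m %in% c(-1L, 0L, 1L)) {
    stop("rank-1 tensor component m must be -1, 0 or +1, got ", m,
         call. = FALSE)
  }
  ops <- spin_matrices(s)
  switch(as.character(m),
    "1"  = -ops$Iplus / sqrt(2),
    "0"  = ops$Iz,
    "-1" = ops$Iminus / sqrt(2)
  )
}

#' Embed a single-site operator into a composite Hilbert space
#'
#' Tensor product with the identity on every other site. Sites are ordered as
#' in the reduced spin system; the first site varies slowest (lexicographic
#' product basis), so the last site has unit stride.
#'
#' @param op Single-site matrix (dense or sparse).
#' @param site 1-based site index.
#' @param dims Integer vector of per-site dimensions `2*s_i + 1`.
#' @param sparse Return a sparse `Matrix` (default) or dense base matrix.
#' @return Composite operator of dimension `prod(dims)`.
#' @export
embed_operator <- function(op, site, dims, sparse = TRUE) {
  dims <- as.integer(dims)
  if (site < 1 || site > length(dims)) {
    stop("site index out of range", call. = FALSE)
  }
  if (nrow(op) != dims[site] || ncol(op) != dims[site]) {
    stop("operator dimension ", nrow(op), " does not match site dimension ",
         dims[site], call. = FALSE)
  }
  d_left <- prod(dims[seq_len(site - 1)])
  d_right <- prod(dims[-seq_len(site)])
  out <- Matrix::kronecker(
    Matrix::Diagonal(d_left),
    Matrix::kronecker(Matrix::Matrix(op, sparse = TRUE), Matrix::Diagonal(d_right))
  )
  out <- methods::as(out, "CsparseMatrix")
  if (!sparse) out <- as.matrix(out)
  out
}

#' Scalar product of the spin operators on two sites
#'
#' `I_a . I_b = Ix_a Ix_b + Iy_a Iy_b + Iz_a Iz_b`, assembled as
#' `Iz_a Iz_b + (I+_a I-_b + I-_a I+_b)/2` so the result is exactly real.
#'
#' @param site_a,site_b Distinct 1-based site indices.
#' @param dims Per-site dimensions.
#' @param spins Per-site spin quantum numbers.
#' @return Real sparse composite operator.
#' @export
scalar_coupling_operator <- function(site_a, site_b, dims, spins) {
  if (site_a == site_b) stop("scalar product needs two distinct sites", call. = FALSE)
  oa <- spin_matrices(spins[site_a])
  ob <- spin_matrices(spins[site_b])
  za <- embed_operator(oa$Iz, site_a, dims)
  zb <- embed_operator(ob$Iz, site_b, dims)
  pa <- embed_operator(oa$Iplus, site_a, dims)
  mb <- embed_operator(ob$Iminus, site_b, dims)
  ma <- embed_operator(oa$Iminus, site_a, dims)
  pb <- embed_operator(ob$Iplus, site_b, dims)
  za %*% zb + (pa %*% mb + ma %*% pb) / 2
}

#' Total spin-projection operator F^z of a composite system
#'
#' Sum of the embedded per-site `Iz`. Diagonal in the product basis; its
#' diagonal equals the per-state sum of m values.
#'
#' @param dims Per-site dimensions.
#' @param spins Per-site spins.
#' @return Sparse diagonal composite operator.
#' @export
total_fz_operator <- function(dims, spins) {
  Matrix::Diagonal(x = state_fz(dims, spins))
}

# internal: per-basis-state total Fz (vector of length prod(dims)),
# basis lexicographic with site 1 slowest, m descending within each site.
state_fz <- function(dims, spins) {
  fz <- 0
  for (i in seq_along(dims)) {
    m_i <- spins[i] - (seq_len(dims[i]) - 1)
    d_right <- prod(dims[-seq_len(i)])
    d_left <- prod(dims[seq_len(i - 1)])
    fz <- fz + rep(rep(m_i, each = d_right), times = d_left)
  }
  fz
}
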