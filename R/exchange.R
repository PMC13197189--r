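#' Parahydrogen singlet density matrix
#'
#' The 4x4 density matrix of the two hydride spins in the nuclear singlet
#' state `|S> = (|+-> - |-+>)/sqrt(2)`: trace one, zero magnetization on
#' both spins, expectation of the hydride-pair scalar product -3/4.
#'
#' @return Real 4x4 matrix in the basis `|++>, |+->, |-+>, |-->`.
#' @export
ph2_singlet <- function() {
  m <- matrix(0, 4, 4)
  m[2, 2] <- m[3, 3] <- 0.5
  m[2, 3] <- m[3, 2] <- -0.5
  m
}

# the site-ordering contract: complex = substrate sites, then hydride 1,
# then hydride 2 (hydrides fastest-varying indices)
check_exchange_dims <- function(dims_s, dims_c) {
  nc <- length(dims_c)
  if (length(dims_s) < 1L || nc != length(dims_s) + 2L ||
      !all(dims_c[seq_along(dims_s)] == dims_s) ||
      !all(dims_c[c(nc - 1L, nc)] == 2L)) {
    stop("complex sites must be the substrate sites followed by two ",
         "spin-1/2 hydrides", call. = FALSE)
  }
  invisible(TRUE)
}

#' Partial-trace exchange map over the hydrides
#'
#' Linear map from the complex Liouville space to the substrate Liouville
#' space implementing `rho_S = Tr_H2(rho_C)`: the kinematic part of
#' substrate dissociation. Trace preserving, and conserving the coherence
#' order (nonzero elements only between equal q).
#'
#' @param complex_config `effective_config` (or reduced `spin_system`) of
#'   the complex, whose last two sites are the hydrides.
#' @return A real `superop` of shape `dS^2 x dC^2` (row-major vec bases).
#' @export
partial_trace_map <- function(complex_config) {
  bc <- labeled_basis(complex_config)
  dims_c <- bc$dims
  dims_s <- dims_c[seq_len(length(dims_c) - 2L)]
  check_exchange_dims(dims_s, dims_c)
  dS <- prod(dims_s); dC <- bc$d
  ij <- expand.grid(j = seq_len(dS), i = seq_len(dS))  # j fastest
  rows <- (ij$i - 1L) * dS + ij$j
  tri <- lapply(1:4, function(h) {
    rc <- (ij$i - 1L) * 4L + h
    cc <- (ij$j - 1L) * 4L + h
    cbind(rows, (rc - 1L) * dC + cc)
  })
  tri <- do.call(rbind, tri)
  superop(Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2],
                               x = rep(1, nrow(tri)),
                               dims = c(dS^2, dC^2)))
}

#' Kronecker-attachment exchange map
#'
#' Linear map from the substrate Liouville space to the complex Liouville
#' space implementing `rho_C = rho_S (x) rho_pH2`: the kinematic part of
#' substrate association with a fresh parahydrogen pair. Trace preserving
#' when `tr(pH2) = 1`.
#'
#' @param complex_config Reduced complex (substrate sites + 2 hydrides).
#' @param ph2 4x4 hydride-pair density matrix; defaults to the singlet.
#' @return A real `superop` of shape `dC^2 x dS^2`.
#' @export
kron_map <- function(complex_config, ph2 = ph2_singlet()) {
  if (abs(sum(diag(ph2)) - 1) > 1e-12) {
    stop("parahydrogen state must have unit trace", call. = FALSE)
  }
  bc <- labeled_basis(complex_config)
  dims_c <- bc$dims
  dims_s <- dims_c[seq_len(length(dims_c) - 2L)]
  check_exchange_dims(dims_s, dims_c)
  dS <- prod(dims_s); dC <- bc$d
  nz <- which(ph2 != 0, arr.ind = TRUE)
  ij <- expand.grid(j = seq_len(dS), i = seq_len(dS))
  cols <- (ij$i - 1L) * dS + ij$j
  tri <- lapply(seq_len(nrow(nz)), function(k) {
    h <- nz[k, 1]; hp <- nz[k, 2]
    rc <- (ij$i - 1L) * 4L + h
    cc <- (ij$j - 1L) * 4L + hp
    cbind((rc - 1L) * dC + cc, cols, ph2[h, hp])
  })
  tri <- do.call(rbind, tri)
  superop(Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                               dims = c(dC^2, dS^2)))
}

#' Project an exchange pair onto the ZQC subspaces
#'
#' Rectangular gathers of the two maps between the substrate and complex
#' ZQC index sets. Exact because both maps conserve the coherence order.
#'
#' @param pair List with elements `tr` (dS^2 x dC^2 `superop`) and `kron`
#'   (dC^2 x dS^2 `superop`).
#' @param zqc_s,zqc_c [zqc_index()] objects of substrate and complex.
#' @return List with projected `tr` (`nS x nC`) and `kron` (`nC x nS`).
#' @export
project_exchange <- function(pair, zqc_s, zqc_c) {
  list(tr = project_superoperator(pair$tr, zqc_s, zqc_c),
       kron = project_superoperator(pair$kron, zqc_c, zqc_s))
}

# Direct ZQC-block assembly of the exchange maps (no parent-space
# materialization). Hydride-pair states 2 and 3 carry m = 0, so a
# q-symmetric ph2 keeps everything inside the ZQC subspaces.
exchange_zqc <- function(basis_s, basis_c, ph2 = ph2_singlet()) {
  check_exchange_dims(basis_s$dims, basis_c$dims)
  if (abs(sum(diag(ph2)) - 1) > 1e-12) {
    stop("parahydrogen state must have unit trace", call. = FALSE)
  }
  hyd_m <- c(1, 0, 0, -1)  # hydride-pair Fz per pair state
  nz <- which(ph2 != 0, arr.ind = TRUE)
  if (any(hyd_m[nz[, 1]] != hyd_m[nz[, 2]])) {
    stop("parahydrogen state has coherences between different hydride-",
         "pair Fz values; the ZQC representation cannot carry them",
         call. = FALSE)
  }
  zs <- subspace_index(basis_s, 0)
  zc <- subspace_index(basis_c, 0)
  dC <- basis_c$d
  lookup_c <- function(pos) match(pos, zc$pos)
  # partial trace: substrate element e <- sum_h complex element ((i,h),(j,h))
  tri_tr <- lapply(1:4, function(h) {
    rc <- (zs$ket - 1L) * 4L + h
    cc <- (zs$bra - 1L) * 4L + h
    col <- lookup_c((rc - 1L) * dC + cc)
    cbind(seq_len(zs$n), col)
  })
  tri_tr <- do.call(rbind, tri_tr)
  stopifnot(!anyNA(tri_tr[, 2]))
  S_tr <- Matrix::sparseMatrix(i = tri_tr[, 1], j = tri_tr[, 2],
                               x = rep(1, nrow(tri_tr)),
                               dims = c(zs$n, zc$n))
  tri_kr <- lapply(seq_len(nrow(nz)), function(k) {
    h <- nz[k, 1]; hp <- nz[k, 2]
    rc <- (zs$ket - 1L) * 4L + h
    cc <- (zs$bra - 1L) * 4L + hp
    row <- lookup_c((rc - 1L) * dC + cc)
    cbind(row, seq_len(zs$n), ph2[h, hp])
  })
  tri_kr <- do.call(rbind, tri_kr)
  stopifnot(!anyNA(tri_kr[, 1]))
  S_kr <- Matrix::sparseMatrix(i = tri_kr[, 1], j = tri_kr[, 2],
                               x = tri_kr[, 3], dims = c(zc$n, zs$n))
  list(tr = superop(S_tr), kron = superop(S_kr), zqc_s = zs, zqc_c = zc)
}
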