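# Block-restricted construction of commutation superoperators.
#
# Every generator piece used in this package is a sum of commutation
# superoperators of site operators with a definite Fz shift m: the
# Hamiltonian (m = 0) and the rank-1 spherical tensors (m = -1, 0, +1).
# Such a superoperator maps the coherence-order-q subspace into the
# (q + m) subspace, and restricted to those subspaces it decomposes into
# per-Fz-block Kronecker products of small Hilbert blocks. Assembling the
# restriction directly therefore never materializes the parent Liouville
# operator, which is what makes the ZQC representation scale.

# subspace blocks keyed by doubled bra-Fz, with running offsets matching
# subspace_index() ordering (ascending bra Fz; ket-major within a block)
subspace_blocks <- function(basis, q2) {
  out <- list()
  offset <- 0L
  for (f in basis$fz2_levels) {
    kets <- basis$blocks[[as.character(f + q2)]]
    bras <- basis$blocks[[as.character(f)]]
    if (is.null(kets) || is.null(bras)) next
    out[[as.character(f)]] <- list(f = f, kets = kets, bras = bras,
                                   offset = offset)
    offset <- offset + length(kets) * length(bras)
  }
  attr(out, "total") <- offset
  out
}

# Restriction of X -> T X - X T to coherence-order subspaces, where the
# (embedded, real sparse) operator T shifts Fz by m2/2. Returns a real
# sparse matrix mapping subspace q_from2/2 to subspace (q_from2 + m2)/2,
# in subspace_index() ordering on both sides.
commutation_shift_matrix <- function(Tmat, m2, basis, q_from2 = 0L) {
  q_to2 <- q_from2 + m2
  Tmat <- methods::as(Matrix::Matrix(Tmat, sparse = TRUE), "CsparseMatrix")
  fromb <- subspace_blocks(basis, q_from2)
  tob <- subspace_blocks(basis, q_to2)
  n_from <- attr(fromb, "total")
  n_to <- attr(tob, "total")
  ti <- list(); tj <- list(); tx <- list(); k <- 0L
  add_block <- function(M, row_off, col_off) {
    M <- methods::as(Matrix::Matrix(M, sparse = TRUE), "TsparseMatrix")
    if (length(M@x) == 0) return(invisible())
    k <<- k + 1L
    ti[[k]] <<- M@i + 1L + row_off
    tj[[k]] <<- M@j + 1L + col_off
    tx[[k]] <<- M@x
    invisible()
  }
  for (fb in fromb) {
    f <- fb$f
    # T acting on the ket side: bra block unchanged
    tb <- tob[[as.character(f)]]
    if (!is.null(tb)) {
      Tsub <- Tmat[tb$kets, fb$kets, drop = FALSE]
      if (length(Tsub@x) > 0) {
        add_block(Matrix::kronecker(Tsub, Matrix::Diagonal(length(fb$bras))),
                  tb$offset, fb$offset)
      }
    }
    # -X T acting on the bra side: bra block shifts from f to f - m2
    tb2 <- tob[[as.character(f - m2)]]
    if (!is.null(tb2)) {
      C <- Tmat[fb$bras, tb2$bras, drop = FALSE]
      if (length(C@x) > 0) {
        add_block(-Matrix::kronecker(Matrix::Diagonal(length(fb$kets)),
                                     Matrix::t(C)),
                  tb2$offset, fb$offset)
      }
    }
  }
  if (k == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n_to, n_from)))
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(n_to, n_from))
}

# embedded rank-1 tensor for one site of a reduced system
embedded_tensor <- function(basis, site, m) {
  s <- basis$spins[site]
  embed_operator(spherical_tensor(s, m), site, basis$dims)
}
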