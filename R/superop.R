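#' Superoperators as pairs of real sparse matrices
#'
#' R's sparse matrices are real, while Liouville-space generators are
#' complex. In the conventions used here every building block (commutation
#' superoperator of a real Hamiltonian, spherical-tensor relaxation terms,
#' exchange maps) is exactly real, and the only imaginary content is the
#' `-i` in front of the Hamiltonian superoperator. A `superop` therefore
#' stores a real part `re` and an optional imaginary part `im`, acting as
#' `re + 1i*im` on row-major vectorized operators.
#'
#' @param re Real sparse (or dense) matrix.
#' @param im Optional real matrix of the same shape.
#' @return Object of class `superop`.
#' @keywords internal
superop <- function(re, im = NULL) {
  re <- methods::as(methods::as(Matrix::Matrix(re, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (!is.null(im)) {
    im <- methods::as(methods::as(Matrix::Matrix(im, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    stopifnot(all(dim(re) == dim(im)))
  }
  structure(list(re = re, im = im), class = "superop")
}

#' @export
dim.superop <- function(x) dim(x$re)

#' @export
print.superop <- function(x, ...) {
  cat("<superop> ", nrow(x$re), " x ", ncol(x$re), ", nnz ",
      length(x$re@x) + if (is.null(x$im)) 0L else length(x$im@x),
      if (is.null(x$im)) " (real)" else " (complex)", "\n", sep = "")
  invisible(x)
}

#' Apply a superoperator to a vectorized operator
#'
#' @param S A `superop`.
#' @param v Complex (or real) vector.
#' @return Complex vector `(S$re + 1i*S$im) %*% v`.
#' @export
sop_apply <- function(S, v) {
  vr <- Re(v); vi <- Im(v)
  wr <- as.numeric(S$re %*% vr)
  wi <- as.numeric(S$re %*% vi)
  if (!is.null(S$im)) {
    wr <- wr - as.numeric(S$im %*% vi)
    wi <- wi + as.numeric(S$im %*% vr)
  }
  complex(real = wr, imaginary = wi)
}

#' Dense complex matrix of a superoperator
#'
#' Intended for small systems and tests.
#' @param S A `superop`.
#' @export
sop_as_matrix <- function(S) {
  out <- as.matrix(S$re) + 0i
  if (!is.null(S$im)) out <- out + 1i * as.matrix(S$im)
  out
}

sop_add <- function(A, B) {
  im <- if (is.null(A$im) && is.null(B$im)) NULL else {
    zA <- if (is.null(A$im)) 0 else A$im
    zB <- if (is.null(B$im)) 0 else B$im
    zA + zB
  }
  superop(A$re + B$re, im)
}

# scale by a complex scalar z = a + ib
sop_scale <- function(S, z) {
  a <- Re(z); b <- Im(z)
  im0 <- if (is.null(S$im)) NULL else S$im
  re <- a * S$re - if (!is.null(im0)) b * im0 else 0
  im <- NULL
  if (b != 0 || !is.null(im0)) {
    im <- b * S$re + if (!is.null(im0)) a * im0 else 0
  }
  superop(re, im)
}

sop_zero <- function(nrow, ncol = nrow) {
  superop(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nrow, ncol)))
}

#' Project (gather) a superoperator onto index subsets
#'
#' Because the Liouville ket-bra basis is orthonormal, projection onto a
#' subspace spanned by basis elements is a plain row/column gather.
#'
#' @param S A `superop` on the full Liouville space.
#' @param rows,cols Integer vectors of (row-major) Liouville indices, e.g.
#'   the `pos` field of a [zqc_index()].
#' @return Projected `superop`.
#' @export
project_superoperator <- function(S, rows, cols = rows) {
  rows <- liouville_positions(rows)
  cols <- liouville_positions(cols)
  if (max(rows) > nrow(S$re) || max(cols) > ncol(S$re)) {
    stop("projection indices exceed superoperator dimensions", call. = FALSE)
  }
  superop(S$re[rows, cols, drop = FALSE],
          if (is.null(S$im)) NULL else S$im[rows, cols, drop = FALSE])
}

liouville_positions <- function(x) {
  if (is.list(x) && !is.null(x$pos)) as.integer(x$pos) else as.integer(x)
}
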