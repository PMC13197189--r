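#' Labeled Hilbert basis of a (reduced) spin system
#'
#' The product basis in declaration order (first site slowest, m descending
#' within a site), with the total spin projection Fz of every state. Half-
#' integer Fz values are tracked internally as doubled integers so block
#' keys are exact.
#'
#' @param system A (reduced) `spin_system` or an `effective_config`.
#' @return Object of class `labeled_basis` with fields `dims`, `spins`,
#'   `d`, `fz` (numeric), `fz2` (doubled integers) and `blocks` (Hilbert
#'   indices per Fz value, ascending Fz).
#' @export
labeled_basis <- function(system) {
  system <- as_reduced_system(system)
  dims <- system_dims(system)
  spins <- system_spins(system)
  fz <- state_fz(dims, spins)
  fz2 <- as.integer(round(2 * fz))
  lev <- sort(unique(fz2))
  blocks <- lapply(lev, function(l) which(fz2 == l))
  names(blocks) <- as.character(lev)
  structure(list(dims = dims, spins = spins, d = prod(dims),
                 labels = system$nuclei$label, fz = fz, fz2 = fz2,
                 fz2_levels = lev, blocks = blocks),
            class = "labeled_basis")
}

as_reduced_system <- function(x) {
  if (inherits(x, "effective_config")) x$reduced_system
  else if (inherits(x, "spin_system")) {
    if (length(x$groups) > 0) {
      stop("system still contains equivalence groups; reduce it first ",
           "(enumerate_configs) or pass an effective_config", call. = FALSE)
    }
    x
  } else stop("expected a spin_system or effective_config", call. = FALSE)
}

#' Coherence orders of the Liouville ket-bra basis
#'
#' For the row-major Liouville basis element `|r><c|` (index
#' `(r-1)*d + c`), the coherence order is `q = Fz(r) - Fz(c)`: the
#' eigenvalue of the commutation superoperator of total Fz.
#'
#' @param x A reduced `spin_system`, `effective_config` or `labeled_basis`.
#' @return Numeric vector of length `d^2` in row-major Liouville order.
#' @export
coherence_orders <- function(x) {
  b <- if (inherits(x, "labeled_basis")) x else labeled_basis(x)
  (rep(b$fz2, each = b$d) - rep(b$fz2, times = b$d)) / 2
}

#' Index of a coherence-order subspace of Liouville space
#'
#' Enumerates the ket-bra pairs `|r><c|` with `Fz(r) - Fz(c) = q`, ordered
#' by ascending bra Fz block, then ket index, then bra index. For `q = 0`
#' this is the zero-quantum-coherence (ZQC) basis; other orders are used
#' internally when assembling projected relaxation superoperators.
#'
#' @param basis A `labeled_basis` (or something coercible).
#' @param q Coherence order (can be half-integer when spins differ).
#' @return Object of class `zqc_index`: fields `ket`, `bra` (Hilbert
#'   indices), `pos` (row-major Liouville indices), `fz2` (doubled bra Fz
#'   per element), `n`, `d`.
#' @export
subspace_index <- function(basis, q = 0) {
  b <- if (inherits(basis, "labeled_basis")) basis else labeled_basis(basis)
  q2 <- as.integer(round(2 * q))
  ket <- integer(0); bra <- integer(0); fz2 <- integer(0)
  for (f in b$fz2_levels) {
    kets <- b$blocks[[as.character(f + q2)]]
    bras <- b$blocks[[as.character(f)]]
    if (is.null(kets) || is.null(bras)) next
    ket <- c(ket, rep(kets, each = length(bras)))
    bra <- c(bra, rep(bras, times = length(kets)))
    fz2 <- c(fz2, rep.int(f, length(kets) * length(bras)))
  }
  structure(list(ket = ket, bra = bra, pos = (ket - 1L) * b$d + bra,
                 fz2 = fz2, q = q, n = length(ket), d = b$d),
            class = "zqc_index")
}

#' @rdname subspace_index
#' @param x A reduced system, config or basis.
#' @export
zqc_index <- function(x) subspace_index(x, 0)

#' @export
print.zqc_index <- function(x, ...) {
  cat("<zqc_index> q = ", x$q, ", ", x$n, " of ", x$d^2,
      " Liouville elements\n", sep = "")
  invisible(x)
}

#' Dimension of the zero-quantum-coherence subspace
#'
#' Evaluates the closed-form count: the per-Fz Hilbert-block dimensions are
#' the convolution of the per-site m-degeneracies, and the ZQC dimension is
#' the sum of their squares. For `n_noneq` spin-1/2 nuclei and effective
#' spins `k_values` this generalizes the single-group formula to any number
#' of groups.
#'
#' @param n_noneq Number of non-equivalent spin-1/2 nuclei (>= 0).
#' @param k_values Numeric vector of effective spins (possibly empty).
#' @return Integer ZQC dimension.
#' @examples
#' zqc_dimension(3, 3/2)   # 196: acetonitrile substrate at K = 3/2
#' zqc_dimension(5, 3/2)   # 2838: the corresponding SABRE complex
#' @export
zqc_dimension <- function(n_noneq, k_values = numeric(0)) {
  degs <- c(rep(list(c(1, 1)), n_noneq),
            lapply(k_values, function(k) rep(1, round(2 * k + 1))))
  if (length(degs) == 0) return(1L)
  conv <- Reduce(function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(b)) out[i:(i + length(a) - 1)] <-
        out[i:(i + length(a) - 1)] + a * b[i]
    out
  }, degs)
  as.integer(round(sum(conv^2)))
}

zqc_dimension_system <- function(system) {
  system <- as_reduced_system(system)
  spins <- system_spins(system)
  zqc_dimension(sum(spins == 0.5), spins[spins != 0.5])
}

#' Liouville-space dimensions of the three SABRE representations
#'
#' For a SABRE model (substrate of N spins, complex of N+2), reports per
#' effective-spin configuration the dimension of the full unreduced matrix
#' `4^N + 4^(N+2)`, of the effective-spin-reduced (K-SABRE) matrix
#' `prod(2K_i+1)^2 (4^(N-P) + 4^(N-P+2))`, and of the ZQC-reduced matrix
#' (sum of the substrate and complex ZQC subspace dimensions).
#'
#' @param model A `sabre_model`.
#' @return Tibble with one row per configuration (`config`, `weight`,
#'   `k_reduced`, `zqc_substrate`, `zqc_complex`, `zqc`) plus attributes
#'   `full` (scalar) and `maxima` (named vector of the per-representation
#'   maxima, as reported in benchmark tables).
#' @export
matrix_dimensions <- function(model) {
  stopifnot(inherits(model, "sabre_model"))
  N <- nrow(model$substrate$nuclei)
  P <- sum(lengths(lapply(model$substrate$groups, `[[`, "members")))
  full <- 4^N + 4^(N + 2)
  configs <- enumerate_configs(model$substrate)
  rows <- purrr::map_dfr(configs, function(cfg) {
    kfac <- prod((2 * cfg$k_values + 1)^2)
    spins_s <- system_spins(cfg$reduced_system)
    zs <- zqc_dimension(sum(spins_s == 0.5), spins_s[spins_s != 0.5])
    zc <- zqc_dimension(sum(spins_s == 0.5) + 2, spins_s[spins_s != 0.5])
    tibble::tibble(
      config = cfg$label, weight = cfg$weight,
      k_reduced = kfac * (4^(N - P) + 4^(N - P + 2)),
      zqc_substrate = zs, zqc_complex = zc, zqc = zs + zc
    )
  })
  attr(rows, "full") <- full
  attr(rows, "maxima") <- c(full = full,
                            k_reduced = max(rows$k_reduced),
                            zqc = max(rows$zqc))
  rows
}

#' Dimension scaling table for group-free substrates
#'
#' Worst-case benchmark: substrates of N non-equivalent spin-1/2 nuclei
#' (complex N+2). The ZQC-to-full ratio approaches `sqrt(pi*N)` for large N.
#'
#' @param nmax Largest substrate size.
#' @return Tibble with `n`, `full`, `zqc`, `ratio`, `ratio_asymptote`.
#' @export
bench_dimensions <- function(nmax) {
  purrr::map_dfr(seq_len(nmax), function(n) {
    full <- 4^n + 4^(n + 2)
    zqc <- zqc_dimension(n) + zqc_dimension(n + 2)
    tibble::tibble(n = n, full = full, zqc = zqc, ratio = full / zqc,
                   ratio_asymptote = sqrt(pi * n))
  })
}
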