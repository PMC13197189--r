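#' @useDynLib zulfsabre, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

REPRESENTATIONS <- c("zqc", "k_reduced", "full")

# ---------------------------------------------------------------------------
# Field-independent generator parts. Field scans and two-stage protocols
# reuse these across B0 values: every superoperator is linear in the
# Zeeman part, so only a sparse-matrix recombination happens per field.
generator_parts <- function(model, config, representation = "zqc",
                            ph2 = ph2_singlet(), full_cap = 1e6) {
  representation <- match.arg(representation, REPRESENTATIONS)
  if (representation == "zqc") {
    return(generator_parts_zqc(model, config, ph2))
  }
  if (representation == "full") {
    sys_s <- expand_physical(model$substrate)
    sys_c <- expand_physical(model$complex)
    N <- nrow(sys_s$nuclei)
    dim_liouville <- 4^N + 4^(N + 2)
    if (dim_liouville > full_cap) {
      stop("full SABRE matrix dimension 4^N + 4^(N+2) = ", dim_liouville,
           " exceeds the cap of ", full_cap,
           "; use the zqc or k_reduced representation", call. = FALSE)
    }
    corr_s <- group_correlation(model$substrate)
    corr_c <- group_correlation(model$complex)
  } else {
    sys_s <- config$reduced_system
    sys_c <- reduce_complex(model, config)
    corr_s <- corr_c <- NULL  # effective spins already carry the group term
  }
  spec_s <- relaxation_spec(sys_s, correlation = corr_s)
  spec_c <- relaxation_spec(sys_c, correlation = corr_c)
  hp_s <- hamiltonian_parts(sys_s)
  hp_c <- hamiltonian_parts(sys_c)
  basis_s <- labeled_basis(sys_s)
  basis_c <- labeled_basis(sys_c)
  nS <- basis_s$d^2; nC <- basis_c$d^2
  Gs <- build_relaxation_superoperator(sys_s, spec_s)$re
  Gc <- build_relaxation_superoperator(sys_c, spec_c)$re
  tr_map <- partial_trace_map(sys_c)$re
  kr_map <- kron_map(sys_c, ph2)$re
  re <- rbind(
    cbind(Gs - model$wa * Matrix::Diagonal(nS), model$kd * tr_map),
    cbind(model$wa * kr_map, Gc - model$kd * Matrix::Diagonal(nC))
  )
  list(representation = representation, model = model, config = config,
       sys_s = sys_s, sys_c = sys_c,
       basis_s = basis_s, basis_c = basis_c, zqc_s = NULL, zqc_c = NULL,
       nS = nS, nC = nC, dS = basis_s$d, dC = basis_c$d,
       re = methods::as(re, "CsparseMatrix"),
       hj = list(s = commutation_superoperator(hp_s$h_j)$re,
                 c = commutation_superoperator(hp_c$h_j)$re),
       hz = list(s = commutation_superoperator(hp_s$h_z)$re,
                 c = commutation_superoperator(hp_c$h_z)$re))
}

generator_parts_zqc <- function(model, config, ph2) {
  sys_s <- config$reduced_system
  sys_c <- reduce_complex(model, config)
  basis_s <- labeled_basis(sys_s)
  basis_c <- labeled_basis(sys_c)
  hp_s <- hamiltonian_parts(sys_s)
  hp_c <- hamiltonian_parts(sys_c)
  zs <- subspace_index(basis_s, 0)
  zc <- subspace_index(basis_c, 0)
  Gs <- build_relaxation_zqc(basis_s, relaxation_spec(sys_s))
  Gc <- build_relaxation_zqc(basis_c, relaxation_spec(sys_c))
  ex <- exchange_zqc(basis_s, basis_c, ph2)
  nS <- zs$n; nC <- zc$n
  re <- rbind(
    cbind(Gs - model$wa * Matrix::Diagonal(nS), model$kd * ex$tr$re),
    cbind(model$wa * ex$kron$re, Gc - model$kd * Matrix::Diagonal(nC))
  )
  list(representation = "zqc", model = model, config = config,
       sys_s = sys_s, sys_c = sys_c,
       basis_s = basis_s, basis_c = basis_c, zqc_s = zs, zqc_c = zc,
       nS = nS, nC = nC, dS = basis_s$d, dC = basis_c$d,
       re = methods::as(re, "CsparseMatrix"),
       hj = list(s = commutation_shift_matrix(hp_s$h_j, 0L, basis_s),
                 c = commutation_shift_matrix(hp_c$h_j, 0L, basis_c)),
       hz = list(s = commutation_shift_matrix(hp_s$h_z, 0L, basis_s),
                 c = commutation_shift_matrix(hp_c$h_z, 0L, basis_c)))
}

# ---------------------------------------------------------------------------

#' Assemble the SABRE master-equation generator
#'
#' Builds the block generator of the coupled substrate/complex system at a
#' constant field: diagonal blocks `L - Wa*1` (substrate) and `L - kd*1`
#' (complex) with `L = -iH + Gamma`, plus off-diagonal exchange couplings
#' `kd * S_TrH2` (complex -> substrate) and `Wa * S_Kron` (substrate ->
#' complex), in the chosen representation. The global trace functional
#' (sum of substrate and complex traces) is a left null vector.
#'
#' @param model A `sabre_model`.
#' @param config An `effective_config` of the substrate (ignored for the
#'   `"full"` representation, which expands all groups and uses fully
#'   correlated local fields within them).
#' @param b0_t Field in tesla.
#' @param representation One of `"zqc"`, `"k_reduced"`, `"full"`.
#' @param full_cap Refusal threshold on the full Liouville dimension
#'   `4^N + 4^(N+2)`.
#' @return A `sabre_generator`.
#' @export
assemble_generator <- function(model, config, b0_t,
                               representation = "zqc",
                               full_cap = 1e6) {
  parts <- generator_parts(model, config, representation, full_cap = full_cap)
  generator_at(parts, b0_t)
}

generator_at <- function(parts, b0_t) {
  gen <- parts
  gen$b0_t <- b0_t
  im <- -Matrix::bdiag(parts$hj$s + b0_t * parts$hz$s,
                       parts$hj$c + b0_t * parts$hz$c)
  gen$im <- methods::as(im, "CsparseMatrix")
  gen$cache <- new.env(parent = emptyenv())
  class(gen) <- "sabre_generator"
  gen
}

#' @export
print.sabre_generator <- function(x, ...) {
  cat("<sabre_generator> ", x$representation, " representation, dim ",
      x$nS, " + ", x$nC, ", B0 = ", format(x$b0_t), " T\n", sep = "")
  invisible(x)
}

#' Generator as a dense complex matrix (small systems)
#'
#' @param gen A `sabre_generator`.
#' @param cap Maximum total dimension.
#' @export
generator_matrix <- function(gen, cap = 4096) {
  n <- gen$nS + gen$nC
  if (n > cap) stop("generator dimension ", n, " above cap", call. = FALSE)
  as.matrix(gen$re) + 1i * as.matrix(gen$im)
}

# cached norm figures steering the propagator
generator_norms <- function(gen) {
  if (is.null(gen$cache$alpha)) {
    gen$cache$alpha <- 1.15 * cpp_power_norm(gen$re, gen$im)
    gen$cache$dnorm <- max(Matrix::colSums(abs(gen$re)))
  }
  list(alpha = gen$cache$alpha, dnorm = gen$cache$dnorm)
}

# ---------------------------------------------------------------------------

#' Initial (unpolarized) SABRE state
#'
#' Identity density matrices with concentration normalization:
#' `tr(rho_S) = 1/(1+cs)` and `tr(rho_C) = cs/(1+cs)`. Diagonal operators
#' live entirely inside the ZQC subspace, so the state is exact in every
#' representation.
#'
#' @param gen A `sabre_generator`.
#' @return A `sabre_state` (stacked Liouville vector with metadata).
#' @export
initial_state <- function(gen) {
  cs <- gen$model$cs
  tr_s <- 1 / (1 + cs)
  tr_c <- cs / (1 + cs)
  vS <- complex(length.out = gen$nS)
  vC <- complex(length.out = gen$nC)
  if (gen$representation == "zqc") {
    vS[gen$zqc_s$ket == gen$zqc_s$bra] <- tr_s / gen$dS
    vC[gen$zqc_c$ket == gen$zqc_c$bra] <- tr_c / gen$dC
  } else {
    vS[(seq_len(gen$dS) - 1L) * gen$dS + seq_len(gen$dS)] <- tr_s / gen$dS
    vC[(seq_len(gen$dC) - 1L) * gen$dC + seq_len(gen$dC)] <- tr_c / gen$dC
  }
  structure(list(representation = gen$representation, vS = vS, vC = vC),
            class = "sabre_state")
}

#' Propagate a SABRE state under a constant-field generator
#'
#' Action of the matrix exponential `exp(G * duration)` on the stacked
#' state. Long coherent evolutions use a Chebyshev expansion (with
#' dissipation-limited substeps); short steps use scaled Taylor expansion.
#' Both schemes verify convergence internally and fall back conservatively,
#' so the result does not depend on the spectral-norm estimates involved.
#'
#' @param gen A `sabre_generator`.
#' @param state A `sabre_state` in the same representation.
#' @param duration Time in seconds (>= 0).
#' @param tol Relative tolerance of the exponential action.
#' @return The propagated `sabre_state`.
#' @export
propagate <- function(gen, state, duration, tol = 1e-9) {
  stopifnot(inherits(gen, "sabre_generator"), inherits(state, "sabre_state"))
  if (!identical(gen$representation, state$representation)) {
    stop("state representation ", state$representation,
         " does not match generator ", gen$representation, call. = FALSE)
  }
  if (duration == 0) return(state)
  if (duration < 0) stop("duration must be non-negative", call. = FALSE)
  v <- c(state$vS, state$vC)
  nrm <- generator_norms(gen)
  mu <- mean(Matrix::diag(gen$re))
  out <- NULL
  z_total <- nrm$alpha * duration
  if (z_total > 80) {
    out <- try_chebyshev(gen, v, duration, tol, nrm, mu)
  }
  if (is.null(out)) {
    res <- cpp_expmv(gen$re, gen$im, Re(v), Im(v), duration, tol,
                     alpha = nrm$alpha + abs(mu))
    out <- complex(real = res$re, imaginary = res$im)
  }
  if (any(!is.finite(Re(out)))) {
    stop("propagation produced non-finite state (B0 = ", gen$b0_t,
         " T, duration = ", duration, " s)", call. = FALSE)
  }
  state$vS <- out[seq_len(gen$nS)]
  state$vC <- out[gen$nS + seq_len(gen$nC)]
  state
}

# Chebyshev attempt; NULL on failure (caller falls back to Taylor)
try_chebyshev <- function(gen, v, duration, tol, nrm, mu) {
  a <- nrm$alpha
  nsub <- max(1L, ceiling((nrm$dnorm + abs(mu)) * duration / 2.5))
  for (attempt in 1:4) {
    z <- a * duration / nsub
    cf <- cheb_exp_coefficients(z, tol)
    res <- cpp_chebmv(gen$re, gen$im, Re(v), Im(v), duration,
                      as.integer(nsub), a, mu, Re(cf), Im(cf), tol)
    if (isTRUE(res$ok)) {
      return(complex(real = res$re, imaginary = res$im))
    }
    nsub <- nsub * 2L
    a <- a * 1.05
  }
  NULL
}

# coefficients c_k = (2 - [k==0]) i^k J_k(z) of exp(i z x) on x in [-1,1];
# Bessel values by Miller's downward recurrence (stable at large order)
cheb_exp_coefficients <- function(z, tol) {
  if (z < 1e-12) return(complex(real = 1))
  kmax <- ceiling(z + 12 * z^(1 / 3) + 30)
  m <- kmax + 40L + as.integer(ceiling(10 * z^(1 / 3)))
  j <- numeric(m + 2)
  j[m + 2] <- 0
  j[m + 1] <- 1e-280
  for (k in m:1) {
    j[k] <- (2 * k / z) * j[k + 1] - j[k + 2]
    if (abs(j[k]) > 1e260) {
      j[k:(m + 2)] <- j[k:(m + 2)] * 1e-260
    }
  }
  norm <- j[1] + 2 * sum(j[seq(3, m + 1, by = 2)])
  j <- j[seq_len(kmax + 1)] / norm
  keep <- max(which(abs(j) > tol * 1e-3), 2)
  j <- j[seq_len(keep)]
  k <- seq_along(j) - 1
  (2 - (k == 0)) * (1i)^k * j
}

state_traces <- function(state, gen) {
  if (state$representation == "zqc") {
    c(s = Re(sum(state$vS[gen$zqc_s$ket == gen$zqc_s$bra])),
      c = Re(sum(state$vC[gen$zqc_c$ket == gen$zqc_c$bra])))
  } else {
    c(s = Re(sum(state$vS[(seq_len(gen$dS) - 1L) * gen$dS + seq_len(gen$dS)])),
      c = Re(sum(state$vC[(seq_len(gen$dC) - 1L) * gen$dC + seq_len(gen$dC)])))
  }
}

# substrate / complex density matrices as dense complex matrices
state_rho_s <- function(state, gen) {
  d <- gen$dS
  if (state$representation == "zqc") {
    rho <- matrix(0i, d, d)
    rho[cbind(gen$zqc_s$ket, gen$zqc_s$bra)] <- state$vS
    rho
  } else {
    matrix(state$vS, d, d, byrow = TRUE)
  }
}

state_rho_c <- function(state, gen) {
  d <- gen$dC
  if (state$representation == "zqc") {
    rho <- matrix(0i, d, d)
    rho[cbind(gen$zqc_c$ket, gen$zqc_c$bra)] <- state$vC
    rho
  } else {
    matrix(state$vC, d, d, byrow = TRUE)
  }
}

# ---------------------------------------------------------------------------

# per-nucleus Iz observables of the (reduced) substrate; group sites are
# reported per nucleus, i.e. <Kz>/P for a group of P protons
substrate_iz_observables <- function(model, config) {
  sys <- config$reduced_system
  basis <- labeled_basis(sys)
  P_of <- stats::setNames(rep(1, nrow(sys$nuclei)), sys$nuclei$label)
  for (g in model$substrate$groups) P_of[g$name] <- length(g$members)
  lapply(stats::setNames(seq_along(basis$dims), sys$nuclei$label), function(i) {
    op <- embed_operator(spin_matrices(basis$spins[i])$Iz, i, basis$dims)
    op / P_of[sys$nuclei$label[i]]
  })
}

# <O>(t) = tr(O rho_S) / tr(rho_S), per configuration
expect_obs <- function(O, state, gen) {
  if (state$representation == "zqc") {
    w <- O[cbind(gen$zqc_s$bra, gen$zqc_s$ket)]
    tr_o <- sum(w * state$vS)
    tr_r <- sum(state$vS[gen$zqc_s$ket == gen$zqc_s$bra])
  } else {
    rho <- matrix(state$vS, gen$dS, gen$dS, byrow = TRUE)
    tr_o <- sum(as.matrix(O) * t(rho))
    tr_r <- sum(diag(rho))
  }
  Re(tr_o / tr_r)
}

# ---------------------------------------------------------------------------

#' Magnetic-field scan of SABRE polarization
#'
#' For each polarization field and each effective-spin configuration,
#' propagates the unpolarized initial state for `tpol` and evaluates the
#' per-nucleus longitudinal polarization of the free substrate (normalized
#' per-configuration expectation values). Group nuclei are reported per
#' nucleus (`<Kz>/P`).
#'
#' @param model A `sabre_model`.
#' @param fields Numeric vector of polarization fields (tesla).
#' @param tpol Polarization time (s).
#' @param representation `"zqc"` (default), `"k_reduced"` or `"full"`.
#' @param tol Propagation tolerance.
#' @param full_cap Dimension guard for the full representation.
#' @return Tibble of class `sabre_scan` with columns `b0_t`, `nucleus`,
#'   `config`, `weight`, `polarization` (one row per field, nucleus and
#'   configuration; the full representation has a single configuration
#'   labeled "full"). Average over configurations with
#'   [average_configs()].
#' @export
field_scan <- function(model, fields, tpol, representation = "zqc",
                       tol = 1e-9, full_cap = 1e6) {
  representation <- match.arg(representation, REPRESENTATIONS)
  if (length(fields) == 0) stop("empty field list", call. = FALSE)
  if (representation == "full") {
    parts <- generator_parts(model, NULL, "full", full_cap = full_cap)
    rows <- purrr::map_dfr(fields, function(b0) {
      gen <- generator_at(parts, b0)
      st <- propagate(gen, initial_state(gen), tpol, tol)
      pol <- full_substrate_polarizations(model, st, gen)
      tibble::tibble(b0_t = b0, nucleus = names(pol), config = "full",
                     weight = 1, polarization = unname(pol))
    })
    class(rows) <- c("sabre_scan", class(rows))
    return(rows)
  }
  configs <- enumerate_configs(model$substrate)
  rows <- purrr::map_dfr(configs, function(cfg) {
    parts <- generator_parts(model, cfg, representation)
    obs <- substrate_iz_observables(model, cfg)
    purrr::map_dfr(fields, function(b0) {
      gen <- generator_at(parts, b0)
      st <- propagate(gen, initial_state(gen), tpol, tol)
      tibble::tibble(
        b0_t = b0, nucleus = names(obs), config = cfg$label,
        weight = cfg$weight,
        polarization = vapply(obs, expect_obs, numeric(1),
                              state = st, gen = gen)
      )
    })
  })
  class(rows) <- c("sabre_scan", class(rows))
  rows
}

# per-nucleus <Iz> of the unreduced substrate, aggregated onto the reduced
# labels (group members are symmetry-equivalent; their mean is the
# per-nucleus polarization)
full_substrate_polarizations <- function(model, state, gen) {
  sys <- gen$sys_s
  basis <- labeled_basis(sys)
  rho <- state_rho_s(state, gen)
  tr_r <- sum(diag(rho))
  vals <- vapply(seq_along(basis$dims), function(i) {
    O <- embed_operator(spin_matrices(0.5)$Iz, i, basis$dims)
    Re(sum(as.matrix(O) * t(rho)) / tr_r)
  }, numeric(1))
  names(vals) <- sys$nuclei$label
  out <- c()
  in_group <- unlist(lapply(model$substrate$groups, `[[`, "members"))
  for (lbl in setdiff(sys$nuclei$label, in_group)) out[lbl] <- vals[lbl]
  for (g in model$substrate$groups) out[g$name] <- mean(vals[g$members])
  out
}

#' Average per-configuration observables with statistical weights
#'
#' Implements the statistical mixture over effective-spin configurations:
#' the physical expectation is the weight-sum of the per-configuration
#' normalized expectations.
#'
#' @param results Tibble from [field_scan()] (columns `config`, `weight`,
#'   `polarization` and grouping columns such as `b0_t`, `nucleus`).
#' @param check_weights Error if the configuration weights do not sum to 1.
#' @return Tibble with one row per grouping-column combination.
#' @export
average_configs <- function(results, check_weights = TRUE) {
  if (check_weights) {
    w <- dplyr::distinct(results, .data$config, .data$weight)
    if (abs(sum(w$weight) - 1) > 1e-12) {
      stop("configuration weights sum to ", sum(w$weight), ", not 1",
           call. = FALSE)
    }
  }
  grouping <- setdiff(names(results), c("config", "weight", "polarization"))
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      polarization = sum(.data$weight * .data$polarization),
      .groups = "drop"
    )
  class(out) <- c("sabre_scan", class(out))
  out
}
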