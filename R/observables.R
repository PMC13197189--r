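#' ZULF detection operator
#'
#' Gamma-weighted total longitudinal magnetization of the substrate,
#' `O = sum_l gamma_l Iz_l`; an effective spin contributes `gamma_P Kz`
#' (the sum of its group members' Iz). This is the quantity a z-axis
#' magnetometer picks up at near-zero field.
#'
#' @param system Reduced `spin_system` or `effective_config`.
#' @return Real sparse composite operator (units of gamma: rad s^-1 T^-1).
#' @export
zulf_observable <- function(system) {
  sys <- as_reduced_system(system)
  basis <- labeled_basis(sys)
  acc <- NULL
  for (i in seq_along(basis$dims)) {
    term <- sys$nuclei$gamma[i] *
      embed_operator(spin_matrices(basis$spins[i])$Iz, i, basis$dims)
    acc <- if (is.null(acc)) term else acc + term
  }
  acc
}

#' Normalized expectation value of a substrate observable
#'
#' `<O> = tr(O rho_S) / tr(rho_S)` for one effective-spin configuration.
#' In the ZQC representation only zero-quantum observables are visible; a
#' non-ZQC observable (e.g. Ix) would be silently biased, so it raises an
#' error instead.
#'
#' @param observable Composite operator on the substrate Hilbert space.
#' @param state A `sabre_state`.
#' @param gen The `sabre_generator` the state belongs to.
#' @return Real expectation value.
#' @export
expectation <- function(observable, state, gen) {
  if (state$representation == "zqc") {
    check_zqc_observable(observable, gen$basis_s)
  }
  expect_obs(observable, state, gen)
}

check_zqc_observable <- function(O, basis, tol = 1e-12) {
  Ot <- methods::as(Matrix::Matrix(O, sparse = TRUE), "TsparseMatrix")
  if (length(Ot@x) == 0) return(invisible(TRUE))
  q <- basis$fz2[Ot@i + 1L] - basis$fz2[Ot@j + 1L]
  bad <- abs(Ot@x) > tol & q != 0L
  if (any(bad)) {
    stop("observable has coherence-order components outside q = 0 ",
         "(max magnitude ", format(max(abs(Ot@x[bad]))),
         "); it is not representable in the ZQC representation",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a two-stage ZULF SABRE free-induction decay
#'
#' Stage 1 polarizes the unpolarized system at `b0_t` for `tpol`; stage 2
#' continues the same master equation (exchange and relaxation stay
#' active, as parahydrogen bubbling is maintained) at the near-zero
#' detection field `b_zulf_t`, sampling the gamma-weighted longitudinal
#' magnetization of the free substrate every `dwell_s`. Configurations are
#' weight-averaged.
#'
#' @param model A `sabre_model`.
#' @param b0_t Polarization field (tesla).
#' @param tpol Polarization time (s); 0 starts detection from the
#'   unpolarized state.
#' @param b_zulf_t Detection field (tesla).
#' @param t_acq Acquisition time (s).
#' @param dwell_s Dwell time (s); must satisfy `dwell_s <= t_acq/2`.
#' @param representation `"zqc"` (default), `"k_reduced"` or `"full"`.
#' @param tol Propagation tolerance.
#' @return Tibble of class `sabre_fid` with columns `time_s`, `signal`,
#'   and protocol metadata in attributes.
#' @export
simulate_fid <- function(model, b0_t, tpol, b_zulf_t, t_acq, dwell_s,
                         representation = "zqc", tol = 1e-9) {
  representation <- match.arg(representation, REPRESENTATIONS)
  if (dwell_s > t_acq / 2) {
    stop("dwell time must be at most t_acq/2", call. = FALSE)
  }
  jmax <- max(abs(model$substrate$j), abs(model$complex$j))
  if (1 / (2 * dwell_s) < 1.2 * jmax) {
    warning("dwell time ", dwell_s, " s gives a Nyquist frequency below ",
            "the largest J coupling; the spectrum may alias", call. = FALSE)
  }
  n_samp <- floor(t_acq / dwell_s) + 1L
  times <- (seq_len(n_samp) - 1L) * dwell_s

  run_cfg <- function(parts, obs_fun) {
    gen_pol <- generator_at(parts, b0_t)
    st <- propagate(gen_pol, initial_state(gen_pol), tpol, tol)
    gen_det <- generator_at(parts, b_zulf_t)
    sig <- numeric(n_samp)
    for (k in seq_len(n_samp)) {
      sig[k] <- obs_fun(st, gen_det)
      if (k < n_samp) st <- propagate(gen_det, st, dwell_s, tol)
    }
    sig
  }

  if (representation == "full") {
    parts <- generator_parts(model, NULL, "full")
    O <- zulf_observable(expand_physical(model$substrate))
    signal <- run_cfg(parts, function(st, gen) expect_obs(O, st, gen))
  } else {
    configs <- enumerate_configs(model$substrate)
    signal <- 0
    for (cfg in configs) {
      parts <- generator_parts(model, cfg, representation)
      O <- zulf_observable(cfg)
      if (representation == "zqc") check_zqc_observable(O, parts$basis_s)
      sig <- run_cfg(parts, function(st, gen) expect_obs(O, st, gen))
      signal <- signal + cfg$weight * sig
    }
  }
  out <- tibble::tibble(time_s = times, signal = signal)
  class(out) <- c("sabre_fid", class(out))
  attr(out, "protocol") <- list(b0_t = b0_t, tpol = tpol,
                                b_zulf_t = b_zulf_t, t_acq = t_acq,
                                dwell_s = dwell_s,
                                representation = representation)
  out
}

#' Fourier-transform an FID into a ZULF spectrum
#'
#' Exponential apodization, zero filling and a discrete Fourier transform
#' of the real-valued signal; one-sided frequency axis. In `"real"` mode a
#' cosine component appears as an absorptive peak; `"magnitude"` mode is
#' phase insensitive.
#'
#' @param fid A `sabre_fid` (or tibble with `time_s`, `signal`).
#' @param apodization_rate Exponential line broadening in s^-1 (adds
#'   `rate/pi` Hz of Lorentzian width); default `1/t_acq`.
#' @param zero_fill Zero-filling factor (>= 1).
#' @param mode `"real"` or `"magnitude"`.
#' @return Tibble of class `sabre_spectrum` with `freq_hz`, `amplitude`.
#' @export
spectrum <- function(fid, apodization_rate = NULL, zero_fill = 2,
                     mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  t <- fid$time_s
  dwell <- t[2] - t[1]
  t_acq <- t[length(t)]
  rate <- apodization_rate %||% (1 / t_acq)
  if (rate < 0) stop("apodization rate must be non-negative", call. = FALSE)
  if (zero_fill < 1) stop("zero_fill must be >= 1", call. = FALSE)
  x <- fid$signal * exp(-rate * t)
  n <- length(x)
  npad <- ceiling(n * zero_fill)
  x <- c(x, rep(0, npad - n))
  F <- stats::fft(x)
  freq <- (seq_len(npad) - 1L) / (npad * dwell)
  keep <- freq <= 1 / (2 * dwell)
  amp <- switch(mode, real = Re(F), magnitude = Mod(F))
  out <- tibble::tibble(freq_hz = freq[keep], amplitude = amp[keep])
  class(out) <- c("sabre_spectrum", class(out))
  attr(out, "processing") <- list(apodization_rate = rate,
                                  zero_fill = zero_fill, mode = mode,
                                  resolution_hz = 1 / (npad * dwell))
  out
}
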