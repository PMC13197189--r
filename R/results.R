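#' Write scan results with a reproducibility sidecar
#'
#' Writes the long-format results table as CSV plus a JSON sidecar holding
#' the metadata needed to reproduce the run (model dimensions,
#' configuration weights, tolerances, package version). Deterministic
#' byte-for-byte on reruns.
#'
#' @param results Tibble (e.g. from [field_scan()]).
#' @param path Output CSV path; the sidecar gets the extension
#'   `.meta.json`.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, meta = list()) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".meta.json")
  payload <- c(list(package = "zulfsabre",
                    version = as.character(utils::packageVersion("zulfsabre")),
                    columns = names(results), rows = nrow(results)),
               meta)
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a SABRE model into a coupling table
#'
#' @param x A `sabre_model`.
#' @param ... Unused.
#' @return Tibble with one row per nonzero coupling in substrate and
#'   complex (`species`, `from`, `to`, `j_hz`).
#' @export
tidy.sabre_model <- function(x, ...) {
  one <- function(sys, species) {
    jm <- sys$j
    idx <- which(upper.tri(jm) & jm != 0, arr.ind = TRUE)
    tibble::tibble(species = species,
                   from = rownames(jm)[idx[, 1]],
                   to = colnames(jm)[idx[, 2]],
                   j_hz = jm[idx])
  }
  dplyr::bind_rows(one(x$substrate, "substrate"), one(x$complex, "complex"))
}

#' Model-level summary: spin counts, kinetics and matrix dimensions
#'
#' @param x A `sabre_model`.
#' @param ... Unused.
#' @export
glance.sabre_model <- function(x, ...) {
  dims <- matrix_dimensions(x)
  mx <- attr(dims, "maxima")
  tibble::tibble(
    n_substrate = nrow(x$substrate$nuclei),
    n_complex = nrow(x$complex$nuclei),
    n_groups = length(x$substrate$groups),
    n_configs = nrow(dims),
    kd = x$kd, cs = x$cs,
    dim_full = unname(mx["full"]),
    dim_k_reduced = unname(mx["k_reduced"]),
    dim_zqc = unname(mx["zqc"])
  )
}

#' Plot a polarization field scan
#'
#' @param object Tibble from [field_scan()] or [average_configs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sabre_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$b0_t * 1e6,
                                    y = .data$polarization,
                                    colour = .data$nucleus)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(B[0] ~ (mu * T)), y = "polarization",
                  colour = "nucleus")
  if ("config" %in% names(object) && length(unique(object$config)) > 1) {
    p <- p + ggplot2::facet_wrap(~config)
  }
  p
}

#' Plot a simulated FID
#'
#' @param object A `sabre_fid`.
#' @param ... Unused.
#' @export
autoplot.sabre_fid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal (arb.)")
}

#' Plot a ZULF spectrum
#'
#' @param object A `sabre_spectrum`.
#' @param ... Unused.
#' @export
autoplot.sabre_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude (arb.)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
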