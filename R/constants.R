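#' Gyromagnetic ratios of common spin-1/2 isotopes
#'
#' Shipped constants table used when a nucleus is declared by isotope tag
#' alone. Values are standard physical constants in rad s^-1 T^-1; a per-
#' nucleus `gamma` in a system definition overrides the table.
#'
#' @format Named numeric vector, rad s^-1 T^-1. Negative for 15N.
#' @export
gyromagnetic_ratios <- c(
  "1H"  =  2.6752218744e8,
  "2H"  =  4.10662791e7,
  "13C" =  6.728284e7,
  "15N" = -2.7126e7,
  "19F" =  2.51814800e8,
  "31P" =  1.08394e8
)

#' Look up a gyromagnetic ratio by isotope tag
#'
#' @param isotope Isotope tag such as `"1H"` or `"15N"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
gamma_of <- function(isotope) {
  g <- gyromagnetic_ratios[isotope]
  if (any(is.na(g))) {
    stop("unknown isotope(s) without explicit gamma: ",
         paste(unique(isotope[is.na(g)]), collapse = ", "), call. = FALSE)
  }
  unname(g)
}

# internal: half-integer check (values representable as n/2)
is_half_integer <- function(x, tol = 1e-9) {
  abs(2 * x - round(2 * x)) < tol
}
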