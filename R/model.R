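#' SABRE model: substrate, complex and exchange kinetics
#'
#' Couples two spin systems through reversible chemical exchange: the free
#' substrate and the transient Ir-dihydride complex consisting of the same
#' substrate nuclei plus two parahydrogen-derived hydrides. The complex
#' carries its own J table and T1 values. Exchange is linear with
#' dissociation rate constant `kd` and association rate `Wa = kd * cs`,
#' with `cs = [C]/[S]` the catalyst-to-substrate concentration ratio.
#'
#' @param substrate `spin_system` of the free substrate (may contain
#'   equivalence groups).
#' @param complex `spin_system` of the complex: the substrate nuclei (same
#'   labels, same declaration order, identical groups) followed by the two
#'   hydrides.
#' @param hydrides Character vector of the two hydride labels in `complex`.
#' @param kd Dissociation rate constant, s^-1 (> 0).
#' @param cs Concentration ratio `[C]/[S]` (> 0).
#' @return Object of class `sabre_model`.
#' @export
sabre_model <- function(substrate, complex, hydrides, kd, cs) {
  validate_spin_system(substrate)
  validate_spin_system(complex)
  if (length(hydrides) != 2L) stop("exactly two hydrides required", call. = FALSE)
  if (!(kd > 0)) stop("kd must be positive", call. = FALSE)
  if (!(cs > 0)) stop("cs = [C]/[S] must be positive", call. = FALSE)
  sub_lab <- substrate$nuclei$label
  cx_lab <- complex$nuclei$label
  if (!all(hydrides %in% cx_lab)) {
    stop("complex is missing hydride nuclei: ",
         paste(setdiff(hydrides, cx_lab), collapse = ", "), call. = FALSE)
  }
  if (!identical(cx_lab, c(sub_lab, hydrides))) {
    stop("complex nuclei must be the substrate nuclei (same order) ",
         "followed by the two hydrides", call. = FALSE)
  }
  if (any(complex$nuclei$spin[match(hydrides, cx_lab)] != 0.5)) {
    stop("hydrides must be spin-1/2", call. = FALSE)
  }
  gs <- lapply(substrate$groups, function(g) g[c("name", "members")])
  gc <- lapply(complex$groups, function(g) g[c("name", "members")])
  if (!identical(gs, gc)) {
    stop("equivalence groups must be identical in substrate and complex ",
         "(magnetic equivalence is conserved during exchange)", call. = FALSE)
  }
  structure(list(substrate = substrate, complex = complex,
                 hydrides = hydrides, kd = kd, cs = cs, wa = kd * cs),
            class = "sabre_model")
}

#' @export
print.sabre_model <- function(x, ...) {
  cat("<sabre_model> substrate ", nrow(x$substrate$nuclei), " spins, complex ",
      nrow(x$complex$nuclei), " spins; kd = ", x$kd, " /s, [C]/[S] = ",
      x$cs, "\n", sep = "")
  invisible(x)
}

# Reduced complex for one effective-spin configuration, with the site
# ordering the exchange maps require: reduced substrate sites first (non-
# equivalent nuclei, then effective spins), hydrides last.
reduce_complex <- function(model, config) {
  red_c <- reduce_system(model$complex, config$k_values)
  target <- c(config$reduced_system$nuclei$label, model$hydrides)
  reorder_system(red_c, target)
}

reorder_system <- function(system, labels) {
  idx <- match(labels, system$nuclei$label)
  if (anyNA(idx) || length(idx) != nrow(system$nuclei)) {
    stop("reorder labels do not match system", call. = FALSE)
  }
  structure(list(nuclei = system$nuclei[idx, ],
                 j = system$j[idx, idx, drop = FALSE],
                 groups = system$groups,
                 shifts_ppm = system$shifts_ppm[labels]),
            class = "spin_system")
}

# physical (group-expanded) systems for the unreduced reference solver
expand_physical <- function(system) {
  structure(list(nuclei = system$nuclei, j = system$j, groups = list(),
                 shifts_ppm = system$shifts_ppm),
            class = "spin_system")
}

# site correlation matrix of the RFF model: fully correlated local fields
# within each equivalence group, uncorrelated otherwise
group_correlation <- function(system) {
  labels <- system$nuclei$label
  C <- diag(1, length(labels))
  for (g in system$groups) {
    idx <- match(g$members, labels)
    C[idx, idx] <- 1
  }
  C
}

#' Load a SABRE model from a structured text configuration file
#'
#' The YAML schema uses unit-suffixed keys throughout (`j_hz`, `t1_s`)
#' because unit mix-ups between Hz, rad/s and tesla are the dominant
#' failure mode in this problem domain. See the shipped fixtures under
#' `inst/extdata` for the layout: a `substrate` section (`nuclei`,
#' `j_hz`, `groups`, optional `shifts_ppm`), a `complex` section
#' (`hydrides` with labels/T1, `j_hz` entries that override or extend the
#' substrate table, `t1_s` overrides), and a `kinetics` section
#' (`kd_s1`, `cs`).
#'
#' @param path File path.
#' @param kd,cs Optional overrides of the kinetic parameters in the file.
#' @return A `sabre_model`.
#' @export
load_model <- function(path, kd = NULL, cs = NULL) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("substrate", "complex")) {
    if (is.null(cfg[[sec]])) {
      stop("model file ", path, ": missing `", sec, "` section", call. = FALSE)
    }
  }
  nuc <- do.call(rbind, lapply(cfg$substrate$nuclei, function(n) {
    data.frame(label = n$label, isotope = n$isotope,
               t1 = n$t1_s %||% NA_real_,
               gamma = n$gamma %||% NA_real_,
               spin = n$spin %||% 0.5, stringsAsFactors = FALSE)
  }))
  j_sub <- jlist_to_df(cfg$substrate$j_hz)
  groups <- lapply(cfg$substrate$groups %||% list(), function(g) {
    list(name = g$name, members = g$members)
  })
  shifts <- unlist(cfg$substrate$shifts_ppm %||% NULL)
  substrate <- spin_system(nuc, j_sub, groups, shifts_ppm = shifts)

  hyd <- cfg$complex$hydrides
  if (is.null(hyd) || length(hyd) != 2) {
    stop("model file ", path, ": complex section must declare exactly two ",
         "hydrides", call. = FALSE)
  }
  hyd_nuc <- do.call(rbind, lapply(hyd, function(n) {
    data.frame(label = n$label, isotope = n$isotope %||% "1H",
               t1 = n$t1_s %||% NA_real_, gamma = n$gamma %||% NA_real_,
               spin = 0.5, stringsAsFactors = FALSE)
  }))
  nuc_c <- rbind(nuc, hyd_nuc)
  t1_over <- cfg$complex$t1_s %||% list()
  for (lbl in names(t1_over)) {
    nuc_c$t1[nuc_c$label == lbl] <- t1_over[[lbl]]
  }
  j_c <- rbind(j_sub, jlist_to_df(cfg$complex$j_hz))
  # later entries win: complex couplings override substrate values
  key <- apply(j_c[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
  j_c <- j_c[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  complex <- spin_system(nuc_c, j_c, groups, shifts_ppm = shifts)

  kin <- cfg$kinetics %||% list()
  sabre_model(substrate, complex,
              hydrides = vapply(hyd, `[[`, "", "label"),
              kd = kd %||% kin$kd_s1 %||% 10,
              cs = cs %||% kin$cs %||% 0.1)
}

jlist_to_df <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      j_hz = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(e) {
    data.frame(from = as.character(e[[1]]), to = as.character(e[[2]]),
               j_hz = as.numeric(e[[3]]), stringsAsFactors = FALSE)
  }))
}

#' Shipped example models
#'
#' Loads one of the SABRE models distributed with the package:
#' `"acetonitrile_15N13C2"` (6 substrate spins: 1-15N, 2-13C, 3-13C and a
#' CH3 group; complex of 8 spins) or `"butyronitrile_15N13C4"` (12
#' substrate spins with two CH2 groups and one CH3 group; complex of 14
#' spins). Coupling constants and T1 times are literature-based
#' reconstructions for these isotopologues and typical Ir-dihydride
#' complexes; see the file comments for provenance of each value.
#'
#' @param name Fixture name.
#' @param kd,cs Optional kinetic-parameter overrides.
#' @return A `sabre_model`.
#' @export
sabre_fixture <- function(name = c("acetonitrile_15N13C2",
                                   "butyronitrile_15N13C4"),
                          kd = NULL, cs = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "zulfsabre")
  if (path == "") stop("fixture not found: ", name, call. = FALSE)
  load_model(path, kd = kd, cs = cs)
}
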