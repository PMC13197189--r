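#' Define a spin system
#'
#' A spin system is the molecule-level description used throughout the
#' package: an ordered set of nuclei, a symmetric J-coupling table in Hz,
#' and (optionally) groups of magnetically equivalent nuclei that may be
#' replaced by effective spins.
#'
#' @param nuclei Data frame with columns `label` (unique short strings),
#'   `isotope` (tag such as "1H"; used to look up gamma when no `gamma`
#'   column is given), and optionally `gamma` (rad s^-1 T^-1), `spin`
#'   (half-integer, default 1/2) and `t1` (longitudinal relaxation time in
#'   seconds; `NA` means no relaxation for that site).
#' @param j Couplings in Hz. Either a symmetric matrix with dimnames equal
#'   to the labels, or a data frame with columns `from`, `to`, `j_hz`
#'   (unlisted pairs default to 0).
#' @param groups List of magnetically equivalent groups; each element is a
#'   list with `name` and `members` (character vector of nucleus labels,
#'   length >= 2). Members must share isotope, gamma, spin 1/2 and t1, and
#'   must couple identically to every external nucleus.
#' @param shifts_ppm Optional named numeric vector of isotropic chemical
#'   shifts in ppm (default 0; at ultralow field these matter only if you
#'   say so).
#' @return An object of class `spin_system`.
#' @seealso [validate_spin_system()], [enumerate_configs()]
#' @export
spin_system <- function(nuclei, j = NULL, groups = list(), shifts_ppm = NULL) {
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  if (nrow(nuclei) == 0L) {
    stop("a spin system needs at least one nucleus", call. = FALSE)
  }
  if (is.null(nuclei$label) || is.null(nuclei$isotope)) {
    stop("`nuclei` needs at least `label` and `isotope` columns", call. = FALSE)
  }
  nuclei$label <- as.character(nuclei$label)
  if (is.null(nuclei$spin)) nuclei$spin <- 0.5
  if (is.null(nuclei$t1)) nuclei$t1 <- NA_real_
  if (is.null(nuclei$gamma)) nuclei$gamma <- NA_real_
  missing_gamma <- is.na(nuclei$gamma)
  if (any(missing_gamma)) {
    nuclei$gamma[missing_gamma] <- gamma_of(nuclei$isotope[missing_gamma])
  }
  labels <- nuclei$label

  jmat <- matrix(0, length(labels), length(labels),
                 dimnames = list(labels, labels))
  if (!is.null(j)) {
    if (is.matrix(j)) {
      if (is.null(dimnames(j))) stop("J matrix needs label dimnames", call. = FALSE)
      jmat[rownames(j), colnames(j)] <- j
    } else {
      j <- as.data.frame(j)
      for (r in seq_len(nrow(j))) {
        a <- as.character(j$from[r]); b <- as.character(j$to[r])
        if (!a %in% labels || !b %in% labels) {
          stop("J table refers to unknown label: ", a, "-", b, call. = FALSE)
        }
        jmat[a, b] <- j$j_hz[r]
        jmat[b, a] <- j$j_hz[r]
      }
    }
  }

  shifts <- stats::setNames(rep(0, length(labels)), labels)
  if (!is.null(shifts_ppm)) shifts[names(shifts_ppm)] <- shifts_ppm

  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (is.character(g)) g <- list(members = g)
    if (is.null(g$name)) g$name <- paste0("K", i)
    g$members <- as.character(g$members)
    g
  })

  sys <- structure(
    list(nuclei = tibble::as_tibble(nuclei), j = jmat, groups = groups,
         shifts_ppm = shifts),
    class = "spin_system"
  )
  validate_spin_system(sys)
}

#' @export
print.spin_system <- function(x, ...) {
  ngrp <- length(x$groups)
  cat("<spin_system> ", nrow(x$nuclei), " nuclei (",
      paste(x$nuclei$isotope, collapse = ", "), ")",
      if (ngrp) paste0(", ", ngrp, " equivalence group(s)") else "", "\n",
      sep = "")
  invisible(x)
}

#' Validate a spin system
#'
#' Checks the structural invariants (unique labels, symmetric zero-diagonal
#' J table, disjoint groups) and the magnetic-equivalence condition: every
#' nucleus outside a group must couple identically (relative tolerance
#' `tol`) to each member of that group.
#'
#' @param system A `spin_system`.
#' @param tol Relative tolerance for the equivalence check (config files are
#'   authored, not measured, so the default is tight).
#' @return The system, invisibly unchanged, if valid; otherwise an error
#'   naming the offending pair.
#' @export
validate_spin_system <- function(system, tol = 1e-9) {
  if (!inherits(system, "spin_system")) stop("not a spin_system", call. = FALSE)
  nuc <- system$nuclei
  labels <- nuc$label
  if (anyDuplicated(labels)) {
    stop("duplicate nucleus labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  jm <- system$j
  if (!isTRUE(all.equal(jm, t(jm), tolerance = 0, check.attributes = FALSE))) {
    stop("J table must be symmetric", call. = FALSE)
  }
  if (any(diag(jm) != 0)) stop("J table must have zero diagonal", call. = FALSE)
  if (!all(is_half_integer(nuc$spin)) || any(nuc$spin < 0)) {
    stop("spins must be non-negative half-integers", call. = FALSE)
  }
  if (any(!is.na(nuc$t1) & nuc$t1 <= 0)) {
    stop("T1 times must be positive (or NA for no relaxation)", call. = FALSE)
  }

  members_all <- unlist(lapply(system$groups, `[[`, "members"))
  if (anyDuplicated(members_all)) {
    stop("equivalence groups must be disjoint", call. = FALSE)
  }
  if (!all(members_all %in% labels)) {
    stop("group member not among nuclei: ",
         paste(setdiff(members_all, labels), collapse = ", "), call. = FALSE)
  }

  for (g in system$groups) {
    if (length(g$members) < 2) {
      stop("group ", g$name, " needs at least 2 members", call. = FALSE)
    }
    idx <- match(g$members, labels)
    if (length(unique(nuc$isotope[idx])) != 1 ||
        length(unique(nuc$gamma[idx])) != 1) {
      stop("group ", g$name, " members must share isotope and gamma",
           call. = FALSE)
    }
    if (any(nuc$spin[idx] != 0.5)) {
      stop("group ", g$name, ": equivalent nuclei must be spin-1/2",
           call. = FALSE)
    }
    t1g <- unique(nuc$t1[idx])
    if (length(t1g) != 1) {
      stop("group ", g$name, " members must share T1", call. = FALSE)
    }
    outside <- setdiff(labels, g$members)
    for (m in outside) {
      jj <- jm[m, g$members]
      ref <- jj[1]
      scale <- max(abs(jj), 1e-300)
      if (any(abs(jj - ref) > tol * scale)) {
        bad <- g$members[which.max(abs(jj - ref))]
        stop("magnetic equivalence violated in group ", g$name, ": J(", m,
             ", ", g$members[1], ") = ", ref, " Hz but J(", m, ", ", bad,
             ") = ", jm[m, bad], " Hz", call. = FALSE)
      }
    }
  }
  invisible(system)
}

#' Multiplicity of total spin K in a group of P spin-1/2 nuclei
#'
#' Number of times the irreducible spin-K representation occurs in the
#' P-fold tensor product of spin-1/2 representations. Evaluated exactly as a
#' difference of binomial coefficients, which matches the closed form
#' `(2K+1)/(P/2+K+1) * choose(P, P/2-K)`.
#'
#' @param P Integer group size (>= 1).
#' @param K Half-integer total spin with `Kmin <= K <= P/2`, where `Kmin` is
#'   0 for even P and 1/2 for odd P.
#' @return Integer multiplicity.
#' @examples
#' multiplicity(3, 1/2)   # 2
#' multiplicity(2, 1)     # 1
#' @export
multiplicity <- function(P, K) {
  check_PK(P, K)
  k_idx <- round(P / 2 - K)
  choose(P, k_idx) - if (k_idx >= 1) choose(P, k_idx - 1) else 0
}

#' Statistical weight of the K subspace of an equivalent group
#'
#' `g_K = (2K+1) * multiplicity(P, K) / 2^P`; the weights over all allowed K
#' sum to one.
#'
#' @inheritParams multiplicity
#' @return Numeric weight in `[0, 1]`.
#' @examples
#' statistical_weight(3, 3/2)   # 1/2
#' statistical_weight(2, 0)     # 1/4
#' @export
statistical_weight <- function(P, K) {
  f <- weight_fraction(P, K)
  f[["num"]] / f[["den"]]
}

# exact numerator/denominator of g_K (denominator 2^P)
weight_fraction <- function(P, K) {
  P <- unname(P); K <- unname(K)
  check_PK(P, K)
  c(num = (2 * K + 1) * multiplicity(P, K), den = 2^P)
}

check_PK <- function(P, K) {
  if (P < 1 || P != round(P)) stop("P must be a positive integer", call. = FALSE)
  kmin <- if (P %% 2 == 0) 0 else 0.5
  if (!is_half_integer(K) || K < kmin - 1e-12 || K > P / 2 + 1e-12 ||
      abs((K - kmin) - round(K - kmin)) > 1e-9) {
    stop("K = ", K, " outside the allowed ladder [", kmin, ", ", P / 2,
         "] for P = ", P, call. = FALSE)
  }
  invisible(TRUE)
}

allowed_k_values <- function(P) {
  kmin <- if (P %% 2 == 0) 0 else 0.5
  seq(P / 2, kmin, by = -1)
}

#' Enumerate effective-spin configurations of a spin system
#'
#' Each group of P magnetically equivalent spin-1/2 nuclei is replaced by a
#' single effective spin K, with K running over `P/2, P/2-1, ..., Kmin`.
#' A configuration is one choice of K for every group; its statistical
#' weight is the product of the per-group weights, and the weights over all
#' configurations sum to one exactly.
#'
#' @param system A validated `spin_system`.
#' @return List of `effective_config` objects, each with elements
#'   `k_values` (named by group), `weight`, exact `weight_num`/`weight_den`,
#'   `label`, and `reduced_system` (non-equivalent nuclei in declaration
#'   order followed by one effective nucleus per group, in group order).
#' @examples
#' # a 3-proton methyl group yields two configurations, K = 3/2 and K = 1/2,
#' # with equal weights 1/2
#' @export
enumerate_configs <- function(system) {
  validate_spin_system(system)
  if (length(system$groups) == 0L) {
    cfg <- structure(
      list(k_values = numeric(0), weight = 1, weight_num = 1, weight_den = 1,
           label = "none", reduced_system = system),
      class = "effective_config"
    )
    return(list(cfg))
  }
  k_lists <- lapply(system$groups, function(g) allowed_k_values(length(g$members)))
  names(k_lists) <- vapply(system$groups, `[[`, "", "name")
  grid <- expand.grid(rev(k_lists), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(k_lists)), drop = FALSE]  # first group slowest
  lapply(seq_len(nrow(grid)), function(r) {
    kv <- stats::setNames(as.numeric(grid[r, ]), names(k_lists))
    num <- 1; den <- 1
    for (gi in seq_along(system$groups)) {
      f <- weight_fraction(length(system$groups[[gi]]$members), kv[gi])
      num <- num * f[["num"]]; den <- den * f[["den"]]
    }
    structure(
      list(
        k_values = kv,
        weight = num / den,
        weight_num = num,
        weight_den = den,
        label = paste(names(kv), format_half(kv), sep = "=", collapse = ","),
        reduced_system = reduce_system(system, kv)
      ),
      class = "effective_config"
    )
  })
}

#' @export
print.effective_config <- function(x, ...) {
  cat("<effective_config> ", x$label, "  weight ", x$weight_num, "/",
      x$weight_den, "\n", sep = "")
  invisible(x)
}

format_half <- function(k) {
  ifelse(abs(k - round(k)) < 1e-9, as.character(round(k)),
         paste0(round(2 * k), "/2"))
}

# Replace each group by one effective nucleus of spin K. Non-equivalent
# nuclei keep declaration order; effective nuclei follow in group order.
reduce_system <- function(system, k_values) {
  nuc <- as.data.frame(system$nuclei)
  labels <- nuc$label
  members_all <- unlist(lapply(system$groups, `[[`, "members"))
  keep <- !(labels %in% members_all)
  red <- nuc[keep, , drop = FALSE]
  for (gi in seq_along(system$groups)) {
    g <- system$groups[[gi]]
    idx <- match(g$members, labels)
    red <- rbind(red, data.frame(
      label = g$name, isotope = nuc$isotope[idx[1]],
      spin = k_values[[gi]], t1 = nuc$t1[idx[1]], gamma = nuc$gamma[idx[1]],
      stringsAsFactors = FALSE
    )[, names(red), drop = FALSE])
  }
  newlab <- red$label
  jm <- matrix(0, length(newlab), length(newlab),
               dimnames = list(newlab, newlab))
  old_of <- function(lbl) {
    gi <- match(lbl, vapply(system$groups, `[[`, "", "name"))
    if (is.na(gi)) lbl else system$groups[[gi]]$members[1]
  }
  for (a in seq_along(newlab)) {
    for (b in seq_along(newlab)) {
      if (a == b) next
      jm[a, b] <- system$j[old_of(newlab[a]), old_of(newlab[b])]
    }
  }
  # intra-group couplings vanished with the group; couplings between two
  # groups keep the (uniform) inter-group value picked up above
  shifts <- stats::setNames(rep(0, length(newlab)), newlab)
  common <- intersect(newlab, names(system$shifts_ppm))
  shifts[common] <- system$shifts_ppm[common]
  structure(
    list(nuclei = tibble::as_tibble(red), j = jm, groups = list(),
         shifts_ppm = shifts),
    class = "spin_system"
  )
}

# per-site dimensions / spins of a (reduced) system
system_dims <- function(system) as.integer(round(2 * system$nuclei$spin + 1))
system_spins <- function(system) system$nuclei$spin
hilbert_dim <- function(system) prod(system_dims(system))

#' Random small spin system for testing
#'
#' Draws a system of `n` spin-1/2 nuclei with random J couplings and T1
#' times, optionally including one group of equivalent nuclei (whose
#' external couplings are made identical by construction). Intended for
#' property-style tests; uses the current RNG stream.
#'
#' @param n Number of nuclei (>= 2).
#' @param group_size 0 for no group, otherwise 2..n.
#' @param j_scale Couplings are drawn uniformly from `[-j_scale, j_scale]` Hz.
#' @param isotopes Isotope tags sampled per nucleus.
#' @return A validated `spin_system`.
#' @export
random_spin_system <- function(n, group_size = 0, j_scale = 20,
                               isotopes = c("1H", "13C", "15N")) {
  stopifnot(n >= 2, group_size == 0 || (group_size >= 2 && group_size <= n))
  iso <- sample(isotopes, n, replace = TRUE)
  labels <- paste0("n", seq_len(n))
  groups <- list()
  if (group_size > 0) {
    iso[seq_len(group_size)] <- "1H"
    groups <- list(list(name = "G", members = labels[seq_len(group_size)]))
  }
  nuc <- data.frame(label = labels, isotope = iso,
                    t1 = stats::runif(n, 1, 10), stringsAsFactors = FALSE)
  if (group_size > 0) nuc$t1[seq_len(group_size)] <- nuc$t1[1]
  jm <- matrix(0, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      jm[a, b] <- jm[b, a] <- stats::runif(1, -j_scale, j_scale)
    }
  }
  if (group_size > 0) {
    for (m in setdiff(seq_len(n), seq_len(group_size))) {
      jm[m, seq_len(group_size)] <- jm[m, 1]
      jm[seq_len(group_size), m] <- jm[m, 1]
    }
  }
  spin_system(nuc, jm, groups)
}
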