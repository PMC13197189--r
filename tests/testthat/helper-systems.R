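# shared fixture builders; all randomness is seeded by the calling test

two_spin_substrate <- function(j_hz = -5, t1 = c(20, 5)) {
  spin_system(
    data.frame(label = c("N1", "H1"), isotope = c("15N", "1H"), t1 = t1),
    data.frame(from = "N1", to = "H1", j_hz = j_hz)
  )
}

# minimal SABRE model: substrate + two hydrides; `transfer` toggles the
# substrate-hydride coupling pathway
toy_sabre_model <- function(substrate = two_spin_substrate(), kd = 10,
                            cs = 0.1, transfer = TRUE, hydride_t1 = 1.5) {
  nuc <- as.data.frame(substrate$nuclei)
  nuc_c <- rbind(nuc[, c("label", "isotope", "t1")],
                 data.frame(label = c("Ha", "Hb"), isotope = "1H",
                            t1 = hydride_t1))
  jm <- substrate$j
  idx <- which(upper.tri(jm) & jm != 0, arr.ind = TRUE)
  jc <- data.frame(from = rownames(jm)[idx[, 1]], to = colnames(jm)[idx[, 2]],
                   j_hz = jm[idx])
  jc <- rbind(jc, data.frame(from = "Ha", to = "Hb", j_hz = -7))
  if (transfer) {
    jc <- rbind(jc, data.frame(from = nuc$label[1], to = "Ha", j_hz = -24))
  }
  cx <- spin_system(nuc_c, jc, groups = substrate$groups)
  sabre_model(substrate, cx, c("Ha", "Hb"), kd = kd, cs = cs)
}

# substrate with one group of equivalent protons attached to a carbon
grouped_substrate <- function(p = 2, j_ch = 140, t1 = c(10, 5)) {
  hl <- paste0("Hg", seq_len(p))
  nuc <- data.frame(label = c("C1", hl), isotope = c("13C", rep("1H", p)),
                    t1 = c(t1[1], rep(t1[2], p)))
  j <- data.frame(from = "C1", to = hl, j_hz = j_ch)
  spin_system(nuc, j, groups = list(list(name = "G", members = hl)))
}

expect_close <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}

# dense embedding that also accepts complex single-site operators
embed_dense <- function(op, site, dims) {
  A <- 1
  for (k in seq_along(dims)) {
    A <- kronecker(A, if (k == site) op else diag(dims[k]))
  }
  A
}

substrate_iz_observables_for <- function(m, cfg, repn) {
  if (repn == "full") {
    sys <- zulfsabre:::expand_physical(m$substrate)
    basis <- labeled_basis(sys)
    lapply(seq_along(basis$dims), function(i) {
      embed_operator(spin_matrices(0.5)$Iz, i, basis$dims)
    })
  } else {
    zulfsabre:::substrate_iz_observables(m, cfg)
  }
}
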