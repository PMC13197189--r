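test_that("model validation enforces the substrate/complex contract", {
  sub <- two_spin_substrate()
  nuc_c <- rbind(as.data.frame(sub$nuclei)[, c("label", "isotope", "t1")],
                 data.frame(label = "Ha", isotope = "1H", t1 = 1))
  cx_onehyd <- spin_system(nuc_c)
  expect_error(sabre_model(sub, cx_onehyd, c("Ha", "Hb"), 10, 0.1),
               "missing hydride")
  expect_error(toy_sabre_model(kd = -1), "kd must be positive")
  expect_error(toy_sabre_model(cs = 0), "cs")
})

test_that("the global trace functional is a left null vector", {
  m <- toy_sabre_model(grouped_substrate(p = 2))
  cfg <- enumerate_configs(m$substrate)[[1]]
  for (repn in c("zqc", "k_reduced")) {
    gen <- assemble_generator(m, cfg, 4e-7, repn)
    G <- generator_matrix(gen, cap = 1e4)
    # trace weights: 1 on diagonal ket-bra positions of each block
    w <- numeric(gen$nS + gen$nC)
    if (repn == "zqc") {
      w[which(gen$zqc_s$ket == gen$zqc_s$bra)] <- 1
      w[gen$nS + which(gen$zqc_c$ket == gen$zqc_c$bra)] <- 1
    } else {
      w[(seq_len(gen$dS) - 1) * gen$dS + seq_len(gen$dS)] <- 1
      w[gen$nS + (seq_len(gen$dC) - 1) * gen$dC + seq_len(gen$dC)] <- 1
    }
    expect_lt(max(Mod(t(w) %*% G)), 1e-9)
  }
})

test_that("kd = 0 limit decouples the species (block-diagonal generator)", {
  # kd must be positive in a model; emulate by comparing off-diagonal blocks
  m <- toy_sabre_model(kd = 10)
  cfg <- enumerate_configs(m$substrate)[[1]]
  gen <- assemble_generator(m, cfg, 4e-7, "zqc")
  G <- gen$re
  off <- G[seq_len(gen$nS), gen$nS + seq_len(gen$nC), drop = FALSE]
  expect_equal(max(abs(off)) > 0, TRUE)  # exchange present
  expect_equal(max(abs(off / m$kd)), 1)  # scales with kd (partial trace 1s)
})

test_that("initial states are unpolarized with concentration traces", {
  m <- toy_sabre_model(cs = 0.25)
  cfg <- enumerate_configs(m$substrate)[[1]]
  for (repn in c("zqc", "k_reduced", "full")) {
    gen <- assemble_generator(m, cfg, 4e-7, repn)
    st <- initial_state(gen)
    tr <- zulfsabre:::state_traces(st, gen)
    expect_close(tr[["s"]], 1 / 1.25, 1e-12)
    expect_close(tr[["c"]], 0.25 / 1.25, 1e-12)
    # every Iz expectation vanishes at t = 0
    obs <- substrate_iz_observables_for(m, cfg, repn)
    for (O in obs) {
      expect_close(zulfsabre:::expect_obs(O, st, gen), 0, 1e-12)
    }
    # q != 0 components are zero by construction
    rho <- zulfsabre:::state_rho_s(st, gen)
    expect_close(rho, diag(diag(rho)), 1e-14)
  }
})

test_that("propagation matches a dense matrix-exponential oracle", {
  m <- toy_sabre_model()
  cfg <- enumerate_configs(m$substrate)[[1]]
  gen <- assemble_generator(m, cfg, 5e-7, "k_reduced")
  G <- generator_matrix(gen, cap = 2048)
  st <- initial_state(gen)
  v <- c(st$vS, st$vC)
  for (t in c(0.05, 1)) {
    w_oracle <- zulfsabre:::expm_dense(G, t) %*% v
    stp <- propagate(gen, st, t)
    expect_close(c(stp$vS, stp$vC), as.vector(w_oracle), 1e-9)
  }
  # zero duration is the identity
  expect_identical(propagate(gen, st, 0), st)
})

test_that("traces are stationary and states stay physical over 10 s", {
  m <- toy_sabre_model()
  cfg <- enumerate_configs(m$substrate)[[1]]
  gen <- assemble_generator(m, cfg, 5e-7, "zqc")
  st <- propagate(gen, initial_state(gen), 10, tol = 1e-12)
  tr <- zulfsabre:::state_traces(st, gen)
  expect_close(tr[["s"]], 1 / 1.1, 1e-10)
  expect_close(tr[["c"]], 0.1 / 1.1, 1e-10)
  for (rho in list(zulfsabre:::state_rho_s(st, gen),
                   zulfsabre:::state_rho_c(st, gen))) {
    expect_close(rho, t(Conj(rho)), 1e-9)
    ev <- eigen((rho + t(Conj(rho))) / 2, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)
  }
})

test_that("without relaxation and exchange the purity is conserved", {
  sys <- two_spin_substrate(t1 = c(NA, NA))
  cfg <- enumerate_configs(sys)[[1]]
  H <- build_hamiltonian(cfg, 5e-7)
  SH <- commutation_superoperator(H)
  set.seed(47)
  psi <- complex(real = rnorm(4), imaginary = rnorm(4))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  rho <- psi %*% t(Conj(psi))
  U <- zulfsabre:::expm_dense(-1i * sop_as_matrix(SH), 2)
  rho_t <- matrix(U %*% as.vector(t(rho)), 4, 4, byrow = TRUE)
  expect_close(sum(diag(rho_t %*% rho_t)), 1, 1e-9)
})

test_that("three representations agree on random small models", {
  set.seed(53)
  for (rep in 1:3) {
    n <- sample(2:3, 1)
    grp <- if (n == 3 && runif(1) < 0.5) 2 else 0
    sub <- if (grp > 0) grouped_substrate(p = 2) else random_spin_system(n)
    m <- toy_sabre_model(sub, kd = runif(1, 5, 50), cs = runif(1, 0.05, 0.5))
    b0 <- runif(1, 1e-7, 2e-6)
    rz <- solve_zqc(m, b0, 0.5, tol = 1e-11)
    rk <- solve_k_reduced(m, b0, 0.5, tol = 1e-11)
    rf <- solve_full(m, b0, 0.5, tol = 1e-11)
    scale <- max(abs(rz$polarization), 1e-6)
    expect_lt(max(abs(rz$polarization - rk$polarization)) / scale, 1e-8)
    expect_lt(max(abs(rz$polarization - rf$polarization)) / scale, 1e-8)
  }
})

test_that("no substrate-hydride coupling means no polarization transfer", {
  m <- toy_sabre_model(transfer = FALSE)
  res <- field_scan(m, c(2e-7, 5e-7, 1e-6), tpol = 1)
  expect_lt(max(abs(res$polarization)), 1e-12)
})

test_that("configuration averaging validates weights and averages", {
  m <- sabre_fixture("acetonitrile_15N13C2")
  res <- field_scan(m, 5e-7, tpol = 0.2)
  avg <- average_configs(res)
  manual <- sum(res$weight[res$nucleus == "N1"] *
                  res$polarization[res$nucleus == "N1"])
  expect_close(avg$polarization[avg$nucleus == "N1"], manual, 1e-12)
  bad <- res
  bad$weight <- bad$weight / 2
  expect_error(average_configs(bad), "sum to")
  # single-config average is the identity
  m0 <- toy_sabre_model()
  r0 <- field_scan(m0, 5e-7, tpol = 0.2)
  a0 <- average_configs(r0)
  j0 <- dplyr::inner_join(a0, r0, by = c("b0_t", "nucleus"),
                          suffix = c("_avg", "_cfg"))
  expect_close(j0$polarization_avg, j0$polarization_cfg, 1e-14)
})

test_that("the full representation refuses oversized systems", {
  m <- sabre_fixture("butyronitrile_15N13C4")
  expect_error(field_scan(m, 5e-7, 0.1, representation = "full"),
               "exceeds the cap")
})
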