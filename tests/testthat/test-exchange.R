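test_that("the parahydrogen singlet has the defining properties", {
  p <- ph2_singlet()
  expect_equal(sum(diag(p)), 1)
  expect_close(p, t(Conj(p)), 1e-15)
  dims <- c(2, 2); spins <- c(1 / 2, 1 / 2)
  # zero magnetization on both hydrides
  for (site in 1:2) {
    iz <- as.matrix(embed_operator(spin_matrices(1 / 2)$Iz, site, dims))
    expect_equal(sum(iz * t(p)), 0)
  }
  # scalar product expectation -3/4 (pure singlet)
  sc <- as.matrix(scalar_coupling_operator(1, 2, dims, spins))
  expect_equal(sum(sc * t(p)), -3 / 4)
})

test_that("partial trace and Kronecker maps compose to the identity", {
  m <- toy_sabre_model()
  cfg <- enumerate_configs(m$substrate)[[1]]
  cx <- zulfsabre:::reduce_complex(m, cfg)
  S_tr <- partial_trace_map(cx)
  S_kr <- kron_map(cx)
  comp <- S_tr$re %*% S_kr$re
  expect_close(as.matrix(comp), diag(nrow(comp)), 1e-12)
  # partial trace of rhoS (x) pH2 returns rhoS for random rhoS
  set.seed(43)
  dS <- 4
  rho <- matrix(rnorm(dS^2), dS) + 1i * matrix(rnorm(dS^2), dS)
  big <- kronecker(rho, ph2_singlet())
  back <- sop_apply(S_tr, as.vector(t(big)))
  expect_close(back, as.vector(t(rho)), 1e-12)
  # trace preservation of the partial trace
  dC <- 16
  rc <- matrix(rnorm(dC^2), dC) + 1i * matrix(rnorm(dC^2), dC)
  out <- matrix(sop_apply(S_tr, as.vector(t(rc))), dS, dS, byrow = TRUE)
  expect_close(sum(diag(out)), sum(diag(rc)), 1e-12)
  expect_error(kron_map(cx, diag(4)), "unit trace")
})

test_that("exchange maps conserve the coherence order", {
  m <- toy_sabre_model(grouped_substrate(p = 2))
  cfg <- enumerate_configs(m$substrate)[[1]]
  sub <- cfg$reduced_system
  cx <- zulfsabre:::reduce_complex(m, cfg)
  q_s <- coherence_orders(sub)
  q_c <- coherence_orders(cx)
  Tr <- methods::as(partial_trace_map(cx)$re, "TsparseMatrix")
  mix <- q_s[Tr@i + 1L] != q_c[Tr@j + 1L]
  expect_equal(sum(abs(Tr@x[mix])), 0)
  Kr <- methods::as(kron_map(cx)$re, "TsparseMatrix")
  mix2 <- q_c[Kr@i + 1L] != q_s[Kr@j + 1L]
  expect_equal(sum(abs(Kr@x[mix2])), 0)
})

test_that("projected exchange blocks are exact and correctly shaped", {
  m <- toy_sabre_model(grouped_substrate(p = 2))
  cfg <- enumerate_configs(m$substrate)[[1]]
  sub <- cfg$reduced_system
  cx <- zulfsabre:::reduce_complex(m, cfg)
  zs <- zqc_index(labeled_basis(sub))
  zc <- zqc_index(labeled_basis(cx))
  pair <- list(tr = partial_trace_map(cx), kron = kron_map(cx))
  proj <- project_exchange(pair, zs, zc)
  expect_equal(dim(proj$tr$re), c(zs$n, zc$n))
  expect_equal(dim(proj$kron$re), c(zc$n, zs$n))
  comp <- proj$tr$re %*% proj$kron$re
  expect_close(as.matrix(comp), diag(zs$n), 1e-12)
  # the direct ZQC assembly agrees with the gathered projection
  ex <- zulfsabre:::exchange_zqc(labeled_basis(sub), labeled_basis(cx))
  expect_close(as.matrix(ex$tr$re) - as.matrix(proj$tr$re),
               matrix(0, zs$n, zc$n), 1e-14)
  expect_close(as.matrix(ex$kron$re) - as.matrix(proj$kron$re),
               matrix(0, zc$n, zs$n), 1e-14)
})

test_that("exchange maps are completely positive and trace preserving", {
  # Choi-matrix positivity, spot-checked on a 2-site substrate
  m <- toy_sabre_model()
  cfg <- enumerate_configs(m$substrate)[[1]]
  cx <- zulfsabre:::reduce_complex(m, cfg)
  dS <- 4; dC <- 16
  for (map in list(list(S = kron_map(cx), din = dS, dout = dC),
                   list(S = partial_trace_map(cx), din = dC, dout = dS))) {
    din <- map$din; dout <- map$dout
    choi <- matrix(0i, din * dout, din * dout)
    for (i in seq_len(din)) for (j in seq_len(din)) {
      E <- matrix(0i, din, din); E[i, j] <- 1
      out <- matrix(sop_apply(map$S, as.vector(t(E))), dout, dout,
                    byrow = TRUE)
      choi[((i - 1) * dout + 1):(i * dout), ((j - 1) * dout + 1):(j * dout)] <-
        out
    }
    ev <- eigen((choi + t(Conj(choi))) / 2, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)
  }
})

test_that("mismatched site ordering is rejected", {
  # complex whose last two sites are not spin-1/2 hydrides
  sys <- spin_system(data.frame(label = c("a", "b", "c"),
                                isotope = c("1H", "1H", "13C")))
  expect_error(partial_trace_map(sys), NA)  # 1H/1H tail is fine
  sys2 <- spin_system(data.frame(label = c("a", "b"), isotope = "1H"))
  expect_error(partial_trace_map(sys2), "substrate sites followed")
})
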