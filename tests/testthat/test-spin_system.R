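test_that("structural validation rejects malformed systems", {
  expect_error(spin_system(data.frame(label = character(0),
                                      isotope = character(0))),
               "at least one nucleus")
  expect_error(
    spin_system(data.frame(label = c("a", "a"), isotope = "1H")),
    "duplicate"
  )
  # asymmetric J matrix
  jm <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(spin_system(data.frame(label = c("a", "b"), isotope = "1H"),
                           jm), "symmetric")
})

test_that("magnetic equivalence of external couplings is enforced", {
  nuc <- data.frame(label = c("X", "p1", "p2", "p3"),
                    isotope = c("13C", "1H", "1H", "1H"))
  j <- data.frame(from = "X", to = c("p1", "p2", "p3"), j_hz = c(7, 6, 7))
  expect_error(
    spin_system(nuc, j, groups = list(list(name = "G",
                                           members = c("p1", "p2", "p3")))),
    "equivalence violated.*p2", perl = TRUE
  )
  # identical couplings are accepted
  j$j_hz <- 7
  sys <- spin_system(nuc, j,
                     groups = list(list(name = "G",
                                        members = c("p1", "p2", "p3"))))
  expect_s3_class(sys, "spin_system")
})

test_that("acetonitrile-like fixture validates and loads", {
  m <- sabre_fixture("acetonitrile_15N13C2")
  expect_equal(nrow(m$substrate$nuclei), 6)
  expect_equal(nrow(m$complex$nuclei), 8)
  expect_equal(length(m$substrate$groups), 1)
  expect_equal(m$substrate$j["C3", "H1"], 136)
  expect_equal(m$substrate$j["N1", "C2"], -18)
})

test_that("multiplicities follow the closed form and count the full space", {
  expect_identical(multiplicity(3, 1 / 2), 2)
  expect_identical(multiplicity(2, 1), 1)
  expect_identical(multiplicity(2, 0), 1)
  expect_identical(multiplicity(1, 1 / 2), 1)
  expect_error(multiplicity(3, 2), "outside")
  # dimension census: sum over K of (2K+1) mu_K = 2^P
  for (P in 1:10) {
    ks <- seq(P / 2, if (P %% 2) 0.5 else 0, by = -1)
    expect_equal(sum((2 * ks + 1) * vapply(ks, multiplicity, 1, P = P)), 2^P)
  }
})

test_that("statistical weights normalize and match known values", {
  expect_equal(statistical_weight(3, 3 / 2), 1 / 2)
  expect_equal(statistical_weight(3, 1 / 2), 1 / 2)
  expect_equal(statistical_weight(2, 1), 3 / 4)
  expect_equal(statistical_weight(2, 0), 1 / 4)
  for (P in 1:10) {
    ks <- seq(P / 2, if (P %% 2) 0.5 else 0, by = -1)
    expect_equal(sum(vapply(ks, statistical_weight, 1, P = P)), 1)
  }
})

test_that("configuration enumeration produces exact product weights", {
  m <- sabre_fixture("butyronitrile_15N13C4")
  cfgs <- enumerate_configs(m$substrate)
  expect_length(cfgs, 8)
  w <- vapply(cfgs, `[[`, 1, "weight")
  labs <- vapply(cfgs, `[[`, "", "label")
  expect_equal(sort(unique(round(w * 128))), c(4, 12, 36))
  expect_equal(w[labs == "K1=1,K2=1,K3=3/2"], 36 / 128)
  expect_equal(w[labs == "K1=0,K2=0,K3=1/2"], 4 / 128)
  # exact rational normalization
  num <- vapply(cfgs, `[[`, 1, "weight_num")
  den <- vapply(cfgs, `[[`, 1, "weight_den")
  expect_true(all(den == 128))
  expect_identical(sum(num), 128)

  # a single CH3 group gives two equal-weight configurations
  ma <- sabre_fixture("acetonitrile_15N13C2")
  cfga <- enumerate_configs(ma$substrate)
  expect_length(cfga, 2)
  expect_equal(vapply(cfga, `[[`, 1, "weight"), c(1 / 2, 1 / 2))

  # group-free system: single configuration of weight one
  cfg0 <- enumerate_configs(two_spin_substrate())
  expect_length(cfg0, 1)
  expect_equal(cfg0[[1]]$weight, 1)
  expect_identical(cfg0[[1]]$reduced_system$j, two_spin_substrate()$j)
})

test_that("reduced systems are valid and ordered deterministically", {
  set.seed(42)
  for (rep in 1:5) {
    sys <- random_spin_system(4, group_size = sample(2:3, 1))
    for (cfg in enumerate_configs(sys)) {
      red <- cfg$reduced_system
      expect_s3_class(validate_spin_system(red), "spin_system")
      # non-equivalent nuclei first (declaration order), group spin last
      expect_equal(red$nuclei$label[nrow(red$nuclei)], "G")
    }
  }
  # weights sum to one exactly for arbitrary group structures
  sys2 <- random_spin_system(5, group_size = 3)
  cf <- enumerate_configs(sys2)
  expect_identical(sum(vapply(cf, `[[`, 1, "weight_num")),
                   cf[[1]]$weight_den)
})
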