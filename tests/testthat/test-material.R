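test_that("strain energy vanishes at identity and matches direct expansion", {
  mats <- table1()
  for (p in mats) {
    expect_identical(strain_energy(p, strain_state(diag(2))), 0)
    expect_identical(strain_energy(p, strain_state(i1 = 3, i2 = 3, jel = 1)), 0)
  }
  # benign tissue at i1 = i2 = 3.01, jel = 1: direct polynomial expansion
  p <- mats$benign
  u_exp <- (p$c10 + p$c01) * 0.01 + p$c11 * 1e-4 + (p$c20 + p$c02) * 1e-4
  expect_equal(strain_energy(p, strain_state(i1 = 3.01, i2 = 3.01, jel = 1)),
               u_exp)
  # tumor, incompressible plane-strain uniaxial stretch 0.9: term-by-term
  lam <- 0.9
  F <- diag(c(1 / lam, lam))
  st <- strain_state(F)
  i1 <- lam^2 + lam^-2 + 1
  a <- i1 - 3
  p <- mats$tumor
  u_exp <- (p$c10 + p$c01) * a + (p$c11 + p$c20 + p$c02) * a^2
  expect_equal(strain_energy(p, st), u_exp, tolerance = 1e-12)
  # compiled path agrees with the invariant-based evaluation
  expect_equal(nlswei:::cpp_strain_energy_F(nlswei:::mat_vec(p), F), u_exp,
               tolerance = 1e-12)
})

test_that("invalid strain states and parameters are rejected", {
  expect_error(strain_state(i1 = 3, i2 = 3, jel = -1),
               class = "nlswei_degenerate_deformation")
  expect_error(strain_state(matrix(c(1, 0, 0, -1), 2, 2)),
               class = "nlswei_degenerate_deformation")
  expect_error(strain_state(i1 = NaN, i2 = 3, jel = 1),
               class = "nlswei_invalid_input")
  expect_error(material_params(-1, -2), class = "nlswei_invalid_input")
  expect_error(material_params(1, 1, poisson_ratio = 0.6),
               class = "nlswei_invalid_input")
  expect_error(material_params(1, 1, density = -5),
               class = "nlswei_invalid_input")
})

test_that("packaged material table reproduces the published coefficients", {
  mats <- load_materials()
  expect_named(mats, c("tumor", "benign"))
  expect_equal(mu0(mats$tumor), 5640)    # 5.64 kPa
  expect_equal(mu0(mats$benign), 1500)   # 1.5 kPa
  expect_equal(mats$tumor$c11, 0.171e6)
  expect_equal(mats$benign$c11, 2.56e3)
  expect_equal(mats$benign$c20, 283)
  expect_equal(mats$tumor$poisson_ratio, 0.495)
  # K0 = 2/D1 consistent with nu = 0.495
  for (p in mats) {
    k0 <- 2 * mu0(p) * 1.495 / (3 * 0.01)
    expect_equal(2 / p$d1, k0, tolerance = 1e-12)
  }
})

test_that("Cauchy stress is zero at identity, symmetric, and equals the
           numerical gradient of the energy at random states", {
  mats <- table1()
  s0 <- cauchy_stress(mats$tumor, strain_state(diag(2)))
  expect_equal(max(abs(s0$sigma)), 0, tolerance = 1e-9 * mu0(mats$tumor))
  for (F in random_F(8)) {
    for (p in mats) {
      sig <- cauchy_stress(p, strain_state(F))
      expect_equal(sig$sigma[1, 2], sig$sigma[2, 1],
                   tolerance = 1e-6 * max(abs(sig$sigma), 1))
      want <- oracle_cauchy(p, F)
      expect_equal(sig$sigma, want,
                   tolerance = 1e-5)
    }
  }
})

test_that("small-strain shear response slope equals mu0", {
  mats <- table1()
  g <- 1e-6
  F <- matrix(c(1, g, 0, 1), 2, 2)
  sig <- cauchy_stress(mats$tumor, strain_state(F))
  expect_equal(sig$sigma[2, 1] / g, 5640, tolerance = 1e-3)
  sig <- cauchy_stress(mats$benign, strain_state(F))
  expect_equal(sig$sigma[2, 1] / g, 1500, tolerance = 1e-3)
})

test_that("energy is invariant under superposed in-plane rotation", {
  mats <- table1()
  for (F in random_F(5, seed = 7)) {
    for (th in c(0.3, 1.2)) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      u1 <- strain_energy(mats$tumor, strain_state(F))
      u2 <- strain_energy(mats$tumor, strain_state(R %*% F))
      expect_equal(u1, u2, tolerance = 1e-10)
    }
  }
})

test_that("tangent shear modulus: closed form at identity, hardening in
           compression, agreement between definitions", {
  mats <- table1()
  id <- strain_state(diag(2))
  expect_equal(tangent_shear_modulus(mats$tumor, id), 5640, tolerance = 1e-3)
  expect_equal(tangent_shear_modulus(mats$benign, id), 1500, tolerance = 1e-3)
  expect_equal(tangent_shear_modulus(mats$tumor, id, mode = "cauchy"), 5640,
               tolerance = 1e-3)
  # 20% uniaxial compression: exceeds the identity value, and matches a
  # brute-force finite difference of the shear stress
  ur <- uniaxial_response(mats$tumor, c(0.2))
  F <- diag(c(ur$lateral_stretch, 0.8))
  st <- strain_state(F)
  gt <- tangent_shear_modulus(mats$tumor, st)
  expect_gt(gt, 5640)
  g <- 1e-5
  sh <- function(gg) matrix(c(1, gg, 0, 1), 2, 2) %*% F
  fd <- (oracle_cauchy(mats$tumor, sh(g))[2, 1] -
           oracle_cauchy(mats$tumor, sh(-g))[2, 1]) / (2 * g)
  expect_equal(gt, fd, tolerance = 1e-2)
  # monotone non-decreasing on [0, 0.30] for both tissues
  for (p in mats) {
    ur <- uniaxial_response(p, seq(0, 0.30, by = 0.05))
    expect_true(all(diff(ur$tangent_modulus) > 0))
    expect_true(all(diff(abs(ur$nominal_stress)) > 0))
  }
})

test_that("uniaxial response: zero at rest, convex hardening, tumor/benign
           ratio grows with strain", {
  mats <- table1()
  ur_t <- uniaxial_response(mats$tumor, c(0, 0.1, 0.3))
  ur_b <- uniaxial_response(mats$benign, c(0, 0.1, 0.3))
  expect_equal(ur_t$nominal_stress[1], 0, tolerance = 1e-6)
  expect_equal(ur_t$tangent_modulus[1], mu0(mats$tumor), tolerance = 1e-3)
  r10 <- ur_t$tangent_modulus[2] / ur_b$tangent_modulus[2]
  r30 <- ur_t$tangent_modulus[3] / ur_b$tangent_modulus[3]
  expect_gt(r10, mu0(mats$tumor) / mu0(mats$benign))
  expect_gt(r30, r10)
  # hardening ratio itself accelerates (convexity)
  for (ur in list(ur_t, ur_b)) {
    g0 <- ur$tangent_modulus[1]
    expect_gt(ur$tangent_modulus[3] / g0, ur$tangent_modulus[2] / g0)
  }
})

test_that("degenerate deformations raise errors from the stress path", {
  mats <- table1()
  expect_error(uniaxial_response(mats$tumor, c(-0.1)),
               class = "nlswei_invalid_input")
  expect_error(uniaxial_response(mats$tumor, c(0.6)),
               class = "nlswei_invalid_input")
})
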