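# Small fixtures keep the nonlinear solves fast; the full phantom is
# exercised by the acceptance suite.

test_that("zero compression returns the identity state with mu0 tangent", {
  fx <- make_test_fixture("inclusion", mu0 = c(1000, 4000), width = 20,
                          height = 10, inclusion_center = c(0, 5),
                          inclusion_diameter = 4)
  st <- solve_compression(fx, 0)
  expect_true(st$converged)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$stress)), 0, tolerance = 1e-4)
  lab <- fx$label[fx$elem_cell]
  expect_equal(st$tangent_modulus[lab == 1L],
               rep(1000, sum(lab == 1L)), tolerance = 1e-3)
  expect_equal(st$tangent_modulus[lab == 2L],
               rep(4000, sum(lab == 2L)), tolerance = 1e-3)
})

test_that("homogeneous block under a full-width frictionless platen is in
           uniform uniaxial compression", {
  fx <- make_test_fixture("homogeneous", width = 20, height = 10,
                          spacing = 1, mu0 = 4000, base_bc = "roller")
  st <- solve_compression(fx, 0.10)
  eyy <- st$F[, 4] - 1
  expect_equal(mean(eyy), -0.10, tolerance = 1e-4)
  expect_lt(diff(range(eyy)), 0.01 * 0.10)   # uniform to 1% of the strain
  # near-incompressibility at nu = 0.495
  J <- st$F[, 1] * st$F[, 4] - st$F[, 2] * st$F[, 3]
  expect_lt(max(abs(J - 1)), 0.02)
  # platen and base reactions balance
  expect_equal(st$platen_force, st$base_force,
               tolerance = 1e-3)
  # frictionless: no horizontal force at contact nodes
  f <- nlswei:::cpp_fem_force(fx$node_xy, fx$elems, fx$elem_mat,
                              nlswei:::mat_matrix(fx$materials),
                              as.numeric(t(st$u)))
  fx_contact <- f[2 * st$contact_nodes - 1]
  expect_lt(max(abs(fx_contact)), 1e-3 * max(abs(f[2 * st$contact_nodes])))
})

test_that("staged and direct solves agree (elastic path independence) and
           energy grows with compression", {
  fx <- make_test_fixture("inclusion", mu0 = c(1000, 4000), width = 20,
                          height = 10, inclusion_center = c(0, 5),
                          inclusion_diameter = 4, base_bc = "fixed")
  sts <- staged_compression(fx, c(0, 0.1, 0.2))
  expect_equal(vapply(sts, function(s) s$compression_level, numeric(1)),
               c(0, 0.1, 0.2))
  st_direct <- solve_compression(fx, 0.2)
  expect_equal(st_direct$u, sts[[3]]$u, tolerance = 1e-5)
  en <- vapply(sts, function(s) s$total_energy, numeric(1))
  expect_true(all(diff(en) > 0))
  # tangent moduli rise with the load for both tissues
  rs <- lapply(sts, roi_statistics, phantom = fx,
               surr_center = c(-6, 5), surr_diameter = 4)
  g_inc <- vapply(rs, function(r) r$modulus[r$tissue == "tumor"], numeric(1))
  g_bg <- vapply(rs, function(r) r$modulus[r$tissue == "surrounding"],
                 numeric(1))
  expect_true(all(diff(g_inc) > 0))
  expect_true(all(diff(g_bg) > 0))
})

test_that("ROI means equal brute-force averages over labelled elements", {
  fx <- make_test_fixture("inclusion", mu0 = c(1000, 4000), width = 20,
                          height = 10, inclusion_center = c(0, 5),
                          inclusion_diameter = 4)
  st <- solve_compression(fx, 0.1)
  rs <- roi_statistics(st, fx, surr_center = c(-6, 5), surr_diameter = 4)
  lab <- fx$label[fx$elem_cell]
  want <- mean(abs(st$F[lab == 2L, 4] - 1))
  expect_equal(rs$strain[rs$tissue == "tumor"], want)
  ec <- element_centers(fx)
  sel <- (ec[, 1] + 0.006)^2 + (ec[, 2] - 0.005)^2 <= 0.002^2 & lab == 1L
  expect_equal(rs$stress[rs$tissue == "surrounding"],
               mean(abs(st$stress[sel, 4])))
  expect_error(roi_statistics(st, fx, surr_center = c(-60, 5)),
               class = "nlswei_invalid_input")
})

test_that("stiff inclusions strain less and carry more stress than the
           background", {
  fx <- make_test_fixture("inclusion", mu0 = c(1000, 4000), width = 30,
                          height = 14, spacing = 1,
                          inclusion_center = c(0, 7),
                          inclusion_diameter = 6, base_bc = "fixed")
  st <- solve_compression(fx, 0.15)
  rs <- roi_statistics(st, fx, surr_center = c(-9, 7), surr_diameter = 6)
  expect_lt(rs$strain[rs$tissue == "tumor"],
            rs$strain[rs$tissue == "surrounding"])
  expect_gt(rs$stress[rs$tissue == "tumor"],
            rs$stress[rs$tissue == "surrounding"])
})

test_that("mesh refinement changes ROI tangent moduli by less than 5%", {
  rs <- lapply(c(2, 1), function(sp) {
    fx <- make_test_fixture("inclusion", mu0 = c(1000, 4000), width = 20,
                            height = 10, spacing = sp,
                            inclusion_center = c(0, 5),
                            inclusion_diameter = 4, base_bc = "fixed")
    st <- solve_compression(fx, 0.15)
    roi_statistics(st, fx, surr_center = c(-6, 5), surr_diameter = 4)
  })
  for (tis in c("tumor", "surrounding")) {
    g <- vapply(rs, function(r) r$modulus[r$tissue == tis], numeric(1))
    expect_lt(abs(g[2] - g[1]) / g[2], 0.05)
  }
})

test_that("out-of-range levels and bad inputs are rejected", {
  fx <- make_test_fixture("homogeneous")
  expect_error(solve_compression(fx, 0.5), class = "nlswei_invalid_input")
  expect_error(staged_compression(fx, c(0.2, 0.1)),
               class = "nlswei_invalid_input")
})
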