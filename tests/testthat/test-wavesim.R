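# Wave-stage tests run on small fixtures at a slightly coarsened output
# grid to stay quick; speeds are checked against c = sqrt(mu/rho).

fixture_record <- function(mu = 4000, width = 60, height = 20,
                           record_ms = 20, out_spacing = 0.25, ...) {
  fx <- make_test_fixture("homogeneous", width = width, height = height,
                          spacing = 1, mu0 = mu, base_bc = "fixed")
  st <- solve_compression(fx, 0)
  simulate_wave(st, fx, record_ms = record_ms, out_spacing = out_spacing, ...)
}

test_that("zero-amplitude excitation yields an identically zero record", {
  rec <- fixture_record(excitation = excitation_spec(amplitude = 0),
                        record_ms = 5)
  expect_identical(max(abs(rec$u)), 0)
  expect_identical(rec$u[1, , ], rec$u[1, , ] * 0)  # zero at t = 0
})

test_that("propagation is linear in the excitation amplitude", {
  r1 <- fixture_record(excitation = excitation_spec(amplitude = 1e6),
                       record_ms = 8)
  r2 <- fixture_record(excitation = excitation_spec(amplitude = 2e6),
                       record_ms = 8)
  expect_equal(r2$u, 2 * r1$u, tolerance = 1e-10)
})

test_that("homogeneous-medium TOF speed tracks sqrt(mu/rho) across moduli", {
  for (mu in c(1000, 4000, 10000, 40000)) {
    c_true <- sqrt(mu / 1000)
    rec <- fixture_record(mu = mu, record_ms = min(30, round(45 / c_true)))
    sp <- tof_speed(directional_filter(rec, "forward"))
    sel <- outer(sp$x > 0.005 & sp$x < 0.022,
                 sp$y > 0.005 & sp$y < 0.016, "&")
    est <- mean(sp$speed[sel], na.rm = TRUE)
    expect_equal(est, c_true, tolerance = 0.03)
  }
})

test_that("record is symmetric about the push line in a symmetric fixture", {
  rec <- fixture_record(record_ms = 10)
  ix0 <- which.min(abs(rec$x))    # push column at x = 0
  off <- 30                        # +- 7.5 mm
  expect_lt(max(abs(rec$u[, ix0 + off, ] - rec$u[, ix0 - off, ])),
            1e-8 * max(abs(rec$u)))
})

test_that("energy stays bounded after the push ends (no attenuation term)", {
  rec <- fixture_record(record_ms = 16)
  # displacement RMS over the domain, after the front leaves the push
  rms <- apply(rec$u, 1, function(m) sqrt(mean(m[rec$mask]^2)))
  late <- rms[seq(41, length(rms))]
  expect_gt(min(late) / max(late), 0.5)
})

test_that("profiles order by distance from the push and match raw columns", {
  rec <- fixture_record(record_ms = 20)
  pr <- extract_profiles(rec, c(10, 13.1), 10)
  expect_identical(pr[[2]], rec$u[, which.min(abs(rec$x - 0.010)),
                                  which.min(abs(rec$y - 0.010))])
  tpk <- vapply(pr[-1], function(u) pr$time[which.max(abs(diff(u)))],
                numeric(1))
  expect_gt(tpk[2], tpk[1])
  expect_error(extract_profiles(rec, 100, 10), class = "nlswei_invalid_input")
})

test_that("layered fixture shows per-layer TOF speeds", {
  fx <- make_test_fixture("layered", mu0 = c(2000, 6000), width = 60,
                          height = 24, spacing = 1, base_bc = "fixed")
  st <- solve_compression(fx, 0)
  rec <- simulate_wave(st, fx, record_ms = 20, out_spacing = 0.25)
  sp <- tof_speed(directional_filter(rec, "forward"))
  xsel <- sp$x > 0.006 & sp$x < 0.022
  v_bot <- mean(sp$speed[xsel, sp$y > 0.003 & sp$y < 0.009], na.rm = TRUE)
  v_top <- mean(sp$speed[xsel, sp$y > 0.015 & sp$y < 0.021], na.rm = TRUE)
  expect_equal(v_bot, sqrt(2), tolerance = 0.08)
  expect_equal(v_top, sqrt(6), tolerance = 0.08)
})

test_that("scalar and vector engines agree on the reconstructed speed", {
  rec_sh <- fixture_record(width = 50, height = 16, record_ms = 14,
                           out_spacing = 0.4)
  rec_psv <- fixture_record(width = 50, height = 16, record_ms = 14,
                            out_spacing = 0.4, engine = "psv")
  sel_speed <- function(rec) {
    sp <- tof_speed(directional_filter(rec, "forward"))
    mean(sp$speed[outer(sp$x > 0.004 & sp$x < 0.018,
                        sp$y > 0.004 & sp$y < 0.013, "&")], na.rm = TRUE)
  }
  expect_equal(sel_speed(rec_sh), sel_speed(rec_psv), tolerance = 0.08)
})

test_that("unconverged states and out-of-domain pushes are rejected", {
  fx <- make_test_fixture("homogeneous")
  st <- solve_compression(fx, 0)
  st$converged <- FALSE
  expect_error(simulate_wave(st, fx), class = "nlswei_invalid_input")
  st$converged <- TRUE
  expect_error(simulate_wave(st, fx,
                             excitation = excitation_spec(center_x = 500)),
               class = "nlswei_invalid_input")
})
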