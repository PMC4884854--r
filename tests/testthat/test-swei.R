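# periodic in both axes (integer cycle counts), the clean spectral oracle
synthetic_plane_wave <- function(direction = 1, nt = 96, nx = 160,
                                 ny = 3, c0 = 2, dt = 2.5e-4, h = 5e-4,
                                 lambda = 8e-3) {
  tt <- (0:(nt - 1)) * dt
  xx <- (0:(nx - 1)) * h
  m <- outer(tt, xx, function(t, x)
    sin(2 * pi * (x - direction * c0 * t) / lambda))
  u <- array(rep(m, ny), dim = c(nt, nx, ny))
  wave_record(u, dt, h)
}

test_that("directional filter passes the kept direction and suppresses the
           other by at least 20 dB", {
  wr <- synthetic_plane_wave(+1)
  wf <- directional_filter(wr, "forward")
  wb <- directional_filter(wr, "backward")
  expect_lt(max(abs(wf$u - wr$u)) / max(abs(wr$u)), 0.05)
  expect_lt(max(abs(wb$u)) / max(abs(wr$u)), 10^(-20 / 20))
  # a standing field splits into its travelling parts
  wl <- synthetic_plane_wave(-1)
  both <- wr
  both$u <- wr$u + wl$u
  ws <- directional_filter(both, "forward")
  expect_lt(max(abs(ws$u - wr$u)) / max(abs(wr$u)), 0.05)
})

test_that("short records are rejected by the filter", {
  wr <- wave_record(array(0, dim = c(4, 4, 1)), 1e-4, 1e-3)
  expect_error(directional_filter(wr), class = "nlswei_invalid_input")
})

test_that("exact synthetic arrivals give the exact speed", {
  # impulses travelling at exactly 2 m/s: u peaks at t = x / c
  nt <- 120; nx <- 150; ny <- 9
  dt <- 2e-4; h <- 4e-4; c0 <- 2
  u <- array(0, dim = c(nt, nx, ny))
  tt <- (0:(nt - 1)) * dt
  for (i in seq_len(nx)) {
    tau <- (i - 1) * h / c0 + 1.47e-3  # off the frame grid
    pulse <- exp(-((tt - tau) / 4e-4)^2)
    for (j in seq_len(ny)) u[, i, j] <- pulse
  }
  wr <- wave_record(u, dt, h)
  # displacement picking: the pulse peak is the arrival itself
  sp <- tof_speed(wr, min_offset = 0.8, front_vmin = 0.5,
                  arrival_on = "displacement")
  v <- sp$speed[20:100, 5]   # columns whose arrival fits in the record
  expect_equal(mean(v, na.rm = TRUE), c0, tolerance = 5e-3)
  expect_lt(sd(v, na.rm = TRUE), 0.02)
})

test_that("piecewise arrival slopes recover layered speeds away from the
           interface", {
  nt <- 200; nx <- 200; ny <- 5
  dt <- 2e-4; h <- 4e-4
  u <- array(0, dim = c(nt, nx, ny))
  tt <- (0:(nt - 1)) * dt
  xs <- (0:(nx - 1)) * h
  # 2 m/s for x < 40 cells, 4 m/s beyond
  tau <- ifelse(xs < 0.016, xs / 2, 0.016 / 2 + (xs - 0.016) / 4) + 1.07e-3
  for (i in seq_len(nx))
    for (j in seq_len(ny)) u[, i, j] <- exp(-((tt - tau[i]) / 4e-4)^2)
  wr <- wave_record(u, dt, h)
  sp <- tof_speed(wr, min_offset = 0.8, front_vmin = 0.5,
                  arrival_on = "displacement")
  expect_equal(mean(sp$speed[15:30, 3], na.rm = TRUE), 2, tolerance = 0.05)
  expect_equal(mean(sp$speed[60:180, 3], na.rm = TRUE), 4, tolerance = 0.05)
})

test_that("modulus map applies G = rho c^2 and preserves the mask", {
  sp <- structure(list(speed = matrix(c(2, NA, 2.449, 1), 2, 2),
                       x = c(0, 1e-3), y = c(0, 1e-3), h = 1e-3,
                       label = matrix(1L, 2, 2),
                       valid = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2),
                       kernels = list(), compression_level = 0,
                       density = 1000), class = "speed_map")
  m <- modulus_map(sp, 1000)
  expect_equal(m$modulus[1, 1], 4000)
  expect_equal(m$modulus[2, 2], 1000)
  expect_equal(m$modulus[1, 2], 6000, tolerance = 1e-3)  # 2.449 m/s -> 6 kPa
  expect_true(is.na(m$modulus[2, 1]))
  expect_error(modulus_map(sp, -1), class = "nlswei_invalid_input")
})

test_that("contrast is exact and validates its inputs", {
  expect_identical(contrast(6, 4), 0.5)
  expect_identical(contrast(5, 5), 0)
  expect_equal(contrast(41, 17), 1.41, tolerance = 1e-2)
  expect_error(contrast(4, 0), class = "nlswei_invalid_input")
  expect_error(contrast(4, NaN), class = "nlswei_invalid_input")
})

test_that("median filter is idempotent on piecewise-constant maps away from
           the jump", {
  m <- matrix(2, 40, 30)
  m[25:40, ] <- 5
  f1 <- nlswei:::cpp_median2d(m, 3L, 3L)
  f2 <- nlswei:::cpp_median2d(f1, 3L, 3L)
  expect_equal(f1, m)            # jump-preserving on clean data
  expect_equal(f2, f1)
})

test_that("directional filtering improves TOF in a reflective fixture", {
  fx <- make_test_fixture("homogeneous", width = 40, height = 16,
                          spacing = 1, mu0 = 4000, base_bc = "fixed")
  st <- solve_compression(fx, 0)
  # long record so the edge reflection re-enters the measurement zone
  rec <- simulate_wave(st, fx, record_ms = 25, out_spacing = 0.25)
  sel_err <- function(r) {
    sp <- tof_speed(r, front_vmin = 0.5)
    sel <- outer(sp$x > 0.004 & sp$x < 0.015, sp$y > 0.004 & sp$y < 0.012, "&")
    abs(mean(sp$speed[sel], na.rm = TRUE) - 2)
  }
  err_filt <- sel_err(directional_filter(rec, "forward"))
  err_raw <- sel_err(rec)
  expect_lt(err_filt, 0.05 * 2)
  expect_lte(err_filt, err_raw)
})

test_that("report assembles ROI summaries and exact contrast", {
  fx <- make_test_fixture("inclusion", mu0 = c(1500, 5640), width = 44,
                          height = 16, spacing = 1,
                          inclusion_center = c(6, 8),
                          inclusion_diameter = 6, base_bc = "fixed")
  st <- solve_compression(fx, 0)
  rec <- simulate_wave(st, fx, record_ms = 24, out_spacing = 0.25,
                       roi = list(surr_center = c(15, 8), surr_diameter = 6))
  mp <- modulus_map(tof_speed(directional_filter(rec, "forward")))
  rep1 <- build_report(list(mp), list(st), fx,
                       surr_center = c(15, 8), surr_diameter = 6)
  expect_s3_class(rep1, "contrast_report")
  gt <- roi_mean(mp, "tumor"); gs <- roi_mean(mp, "surrounding")
  expect_equal(rep1$g_tumor, gt[["mean"]] / 1e3)
  expect_equal(rep1$contrast,
               (gt[["mean"]] - gs[["mean"]]) / gs[["mean"]])
  # level mismatch is an error
  mp2 <- mp; mp2$compression_level <- 0.1
  expect_error(build_report(list(mp2), list(st), fx),
               class = "nlswei_invalid_input")
})
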