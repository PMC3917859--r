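# Synthetic geometry: surfaces, sheets, analytic fixtures.

test_that("hemisphere surrogate matches the closed-form dome area", {
  s <- fix_sphere_fine()
  expect_equal(s$area_cm2, 2 * pi * 10^2 / 100, tolerance = 0.05)
  # total area is exactly the sum of triangle areas
  expect_equal(s$area_cm2, sum(s$triangle_areas_mm2) / 100, tolerance = 1e-9)
})

test_that("mesh edge lengths track the requested target", {
  s <- fix_sphere_fine()
  v <- s$vertices; tr <- s$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  el <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  expect_lt(abs(mean(el) - 1), 0.25)
})

test_that("generated vertices lie exactly on the ellipsoid", {
  s <- make_hemiellipsoid_surface(c(8, 8, 14), 0.8, seed = 3)
  impl <- (s$vertices[, 1] / 8)^2 + (s$vertices[, 2] / 8)^2 +
    (s$vertices[, 3] / 14)^2
  expect_lt(max(abs(impl - 1)), 1e-6)
})

test_that("surface generation is deterministic under a fixed seed", {
  a <- make_hemiellipsoid_surface(c(10, 10, 10), 2, seed = 9)
  b <- make_hemiellipsoid_surface(c(10, 10, 10), 2, seed = 9)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
  c2 <- make_hemiellipsoid_surface(c(10, 10, 10), 2, seed = 10)
  expect_false(identical(a$vertices, c2$vertices))
})

test_that("triangles are wound outward and non-degenerate", {
  s <- fix_sphere()
  expect_true(all(s$triangle_areas_mm2 > 0))
  V <- s$vertices; Tm <- s$triangles
  a <- V[Tm[, 1], ]; e1 <- V[Tm[, 2], ] - a; e2 <- V[Tm[, 3], ] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (a + V[Tm[, 2], ] + V[Tm[, 3], ]) / 3
  expect_true(all(rowSums(nrm * cen) > 0))
})

test_that("degenerate surface inputs are rejected", {
  expect_error(make_hemiellipsoid_surface(c(0, 10, 10), 1), "positive")
  expect_error(make_hemiellipsoid_surface(c(10, 10, 10), 5), "target_edge")
  expect_error(tissue_sheet(8, 32), ">= 16")
  expect_error(tissue_sheet(32, 32, dx = -1), "dx")
})

test_that("tissue sheet reports its area in cm^2", {
  sh <- tissue_sheet(256, 256, dx = 0.25)
  expect_equal(sh$area_cm2, 256 * 256 * 0.25^2 / 100)
})

test_that("spiral field is bounded and respects its symmetries", {
  sh <- tissue_sheet(64, 64, dx = 0.25)
  fx <- spiral_fixture(core = c(31.5, 31.5))
  for (t in c(0, 13, 250)) {
    f <- make_spiral_field(fx, t, sh)
    expect_true(all(f >= fx$v_rest - 1e-9 & f <= fx$v_peak + 1e-9))
  }
  # core voltage is the mean of rest and peak up to the atan2 convention
  fx0 <- spiral_fixture(core = c(31, 31))
  f0 <- make_spiral_field(fx0, 0, sh)
  expect_equal(f0[32, 32], (fx0$v_rest + fx0$v_peak) / 2 +
                 (fx0$v_peak - fx0$v_rest) / 2 * cos(0), tolerance = 1e-9)
  # omega = 0 makes the field static
  fx_static <- spiral_fixture(core = c(31.5, 31.5), omega = 0)
  expect_identical(make_spiral_field(fx_static, 0, sh),
                   make_spiral_field(fx_static, 8, sh))
})

test_that("spiral phase winds once around the core", {
  sh <- tissue_sheet(64, 64, dx = 0.25)
  fx <- spiral_fixture(core = c(31.5, 31.5))
  # numerically integrate the phase gradient on a circle around the core
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- 10
  ph <- atan2(r * sin(ang), r * cos(ang)) -
    fx$wavenumber * (r * sh$dx) - fx$omega * 3
  dph <- diff(c(ph, ph[1]))
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(abs(sum(dph)) / (2 * pi), 1, tolerance = 1e-6)
})

test_that("pulse train yields one upward -20 mV crossing per AP", {
  ap_times <- seq(50, 2900, length.out = 24)
  tr <- make_pulse_train(ap_times, duration = 3000)
  up <- sum(tr$v[-length(tr$v)] < -20 & tr$v[-1] >= -20)
  expect_identical(up, 24L)
  expect_equal(tr$v[1], -85)
  # no APs: constant baseline
  tr0 <- make_pulse_train(numeric(0), duration = 500)
  expect_true(all(tr0$v == -85))
})

test_that("pulse train crossing count equals AP count for random draws", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n_ap <- sample(0:20, 1)
      times <- rand_ap_times(n_ap)
      tr <- make_pulse_train(times, ap_duration = 80, duration = 3000)
      up <- sum(tr$v[-length(tr$v)] < -20 & tr$v[-1] >= -20)
      expect_identical(up, as.integer(n_ap))
    }
  })
})

test_that("overlapping or malformed pulse trains are rejected", {
  expect_error(make_pulse_train(c(100, 150), ap_duration = 80), "overlap")
  expect_error(make_pulse_train(c(2990), ap_duration = 80, duration = 3000),
               "within the trace")
})
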