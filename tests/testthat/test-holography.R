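table1_25nm_geometry <- function() {
  acquisition_geometry(d1_mm = c(10.066, 10.499, 12.226, 15.812),
                       n_projections = 1800, exposure_s = 0.25,
                       photons_per_pixel_projection = 500)
}

test_that("magnification and the Fresnel-scaled geometry", {
  m <- magnification(100, 100, 3)
  expect_equal(m$M, 1)
  expect_equal(m$effective_pixel_nm, 3000)

  total <- calibrate_focus_detector_distance(80.533, 200, 3)
  expect_equal(round(total, 1), 1208.0)
  expect_equal(round(magnification(10.066, total, 3)$effective_pixel_nm), 25)

  expect_error(magnification(-1, 100), "geometry error")
  expect_error(magnification(200, 100), "geometry error")
})

test_that("magnification x effective pixel = detector pixel for all rows", {
  rows <- table1_rows()
  for (i in seq_len(nrow(rows))) {
    for (d1 in rows$d1_mm[[i]]) {
      m <- magnification(d1, 1208, 3)
      expect_equal(m$M * m$effective_pixel_nm, 3000)
      expect_lt(m$distance_eff_mm, d1)
    }
  }
})

test_that("photon budgets reproduce the scan-table arithmetic", {
  expect_equal(photons_per_pixel_scan(1800, 500, 4)$photons_1e6, 3.6)
  expect_equal(photons_per_pixel_scan(2000, 600, 4)$photons_1e6, 4.8)
  r <- photons_per_pixel_scan(1200, 600, 1)
  expect_equal(r$photons, 0.72e6)
  expect_equal(r$photons_1e6, 0.7) # one-decimal reporting convention
  expect_error(photons_per_pixel_scan(0, 500, 4), "parameter error")
})

test_that("Fresnel propagation: plane wave, identity, energy conservation", {
  I <- suppressWarnings(
    fresnel_propagate(matrix(0, 64, 64), NULL, 0.0729, 10, 25))
  expect_equal(max(abs(I - 1)), 0, tolerance = 1e-12)

  amp <- matrix(runif(32 * 32, 0.5, 1.5), 32)
  I0 <- fresnel_propagate(matrix(0, 32, 32), amp, 0.0729, 0, 25)
  expect_equal(I0, amp^2)

  set.seed(1)
  ph <- 0.2 * matrix(sin(seq_len(64) / 5), 64, 64)
  Ip <- suppressWarnings(fresnel_propagate(ph, NULL, 0.0729, 5, 25))
  expect_equal(mean(Ip), 1, tolerance = 1e-6) # Parseval, periodic boundaries
})

test_that("weak sinusoidal phase follows the CTF transfer factor", {
  n <- 256; pix <- 25; lam <- 0.0729; Dmm <- 10
  k <- 8
  f0 <- k / (n * pix)
  phw <- 0.02 * cos(2 * pi * f0 * pix * (0:(n - 1)))
  phm <- matrix(phw[col(matrix(0, n, n))], n, n)
  I <- suppressWarnings(fresnel_propagate(phm, NULL, lam, Dmm, pix))
  got <- 2 * Re(fft(I[1, ])[k + 1]) / n / 0.02
  expected <- 2 * sin(pi * lam * (Dmm * 1e6) * f0^2)
  expect_lt(abs(got - expected) / abs(expected), 0.01)
})

test_that("hologram series: noiseless limit, Poisson statistics, determinism", {
  geom <- table1_25nm_geometry()
  ph <- 0.05 * outer(dnorm(seq(-3, 3, length.out = 96)),
                     dnorm(seq(-3, 3, length.out = 96))) * 2 * pi * 9
  h_inf <- suppressWarnings(
    simulate_hologram_series(ph, geom, rng_seed = 1, photons = Inf))
  direct <- suppressWarnings(
    fresnel_propagate(ph, NULL, geom$wavelength_nm,
                      geom$distance_eff_mm[1], geom$effective_pixel_nm[1]))
  expect_equal(h_inf$images[[1]], direct)
  expect_true(all(vapply(h_inf$flats, function(f) all(f == 1), TRUE)))

  h <- suppressWarnings(simulate_hologram_series(ph, geom, rng_seed = 1))
  flat_mean <- mean(vapply(h$flats, mean, 0))
  expect_lt(abs(flat_mean - 500) / 500, 0.01)

  h2 <- suppressWarnings(simulate_hologram_series(ph, geom, rng_seed = 1))
  expect_identical(h$images, h2$images)
})

test_that("normalization and alignment remove flats, zoom and shifts", {
  # identical magnifications, no shift: stack equals flat-normalized inputs
  img <- matrix(runif(64 * 64, 900, 1100), 64)
  flat <- matrix(1000, 64, 64)
  h <- structure(list(images = list(img, img * 2), flats = list(flat, flat * 2),
                      magnification = c(10, 10), pixel_nm = c(30, 30),
                      distance_eff_mm = c(1, 2), photons = 1000),
                 class = "HologramSet")
  al <- normalize_and_align(h)
  expect_equal(al$stack[[1]], img / 1000)
  expect_equal(al$stack[[2]], img / 1000)
  expect_equal(al$offsets[[2]], c(0, 0), tolerance = 0.05)

  # zero flat pixels are a normalization error
  badflat <- flat; badflat[3, 3] <- 0
  hb <- h; hb$flats[[1]] <- badflat
  expect_error(normalize_and_align(hb), "normalization error")

  # synthetic 2x magnification ratio: coarse rendering realigns to fine
  gauss2d <- function(n, px) {
    x <- (seq_len(n) - (n + 1) / 2) * px
    1 + 0.5 * outer(exp(-x^2 / (2 * 300^2)), exp(-x^2 / (2 * 300^2)))
  }
  fine <- gauss2d(96, 20)
  coarse <- gauss2d(96, 40)
  h2 <- structure(list(images = list(fine, coarse),
                       flats = list(matrix(1, 96, 96), matrix(1, 96, 96)),
                       magnification = c(2, 1), pixel_nm = c(20, 40),
                       distance_eff_mm = c(1, 2), photons = 1),
                  class = "HologramSet")
  al2 <- normalize_and_align(h2)
  ctr <- 25:72 # compare away from the zoom's padded border
  expect_lt(max(abs(al2$stack[[2]][ctr, ctr] - fine[ctr, ctr])), 0.02 * 0.5)

  # known integer shift removed to within half a pixel
  sh <- matrix(0, 96, 96)
  sh[4:96, 1:93] <- fine[1:93, 4:96] # shift by (+3, -3)
  h3 <- h2
  h3$images <- list(fine, sh)
  h3$pixel_nm <- c(20, 20)
  al3 <- normalize_and_align(h3)
  expect_lt(max(abs(al3$offsets[[2]] - c(3, -3))), 0.5)
})

test_that("CTF retrieval: zero contrast, round trip, closed-form maximum", {
  geom <- table1_25nm_geometry()
  ones <- replicate(4, matrix(1, 64, 64), simplify = FALSE)
  ph0 <- ctf_phase_retrieval(ones, geom$wavelength_nm, geom$distance_eff_mm,
                             25)
  expect_equal(max(abs(ph0)), 0, tolerance = 1e-12)

  # simulate -> retrieve round trip on a smooth weak phantom, 256^2 grid
  n <- 256
  x <- seq(-4, 4, length.out = n)
  phase <- 0.1 * outer(exp(-x^2 / 2), exp(-x^2 / 2))
  h <- suppressWarnings(
    simulate_hologram_series(phase, geom, rng_seed = 1, photons = Inf))
  al <- normalize_and_align(h)
  rec <- ctf_phase_retrieval(al$stack, geom$wavelength_nm,
                             al$distance_eff_mm, al$pixel_nm)
  rec <- rec - mean(rec[1:8, 1:8]) # zero-frequency is regularized away
  rmse <- sqrt(mean((rec - phase)^2))
  expect_lt(rmse, 0.1 * diff(range(phase)))

  # single distance at a CTF maximum recovers the amplitude within 2%
  pix <- 25; lam <- geom$wavelength_nm; k <- 6
  f0 <- k / (n * pix)
  Dnm <- 1 / (2 * lam * f0^2) # chi = pi/2 at f0
  a <- 0.05
  phw <- a * cos(2 * pi * f0 * pix * (0:(n - 1)))
  phm <- matrix(phw[col(matrix(0, n, n))], n, n)
  I <- suppressWarnings(fresnel_propagate(phm, NULL, lam, Dnm / 1e6, pix))
  rec1 <- ctf_phase_retrieval(list(I), lam, Dnm / 1e6, pix)
  amp <- 2 * Re(fft(rec1[1, ])[k + 1]) / n
  expect_lt(abs(amp - a) / a, 0.02)
})

test_that("filtered back projection: zero, disk round trip, angle refinement", {
  z <- fbp_reconstruct(matrix(0, 32, 8), seq(0, pi, length.out = 9)[1:8])
  expect_true(all(z$voxels == 0))

  n <- 128
  disk <- disk_mask(n, c(n / 2 + 4, n / 2 - 6), 30) * 1
  angles <- seq(0, pi, length.out = 361)[1:360]
  sino <- radon_project(disk, angles)
  rec <- fbp_reconstruct(sino, angles)$voxels[1, , ]
  support <- disk_mask(n, rep((n + 1) / 2, 2), 50)
  expect_gt(cor(rec[support], disk[support]), 0.95)

  rmse_at <- function(na) {
    ang <- seq(0, pi, length.out = na + 1)[1:na]
    r <- fbp_reconstruct(radon_project(disk, ang), ang)$voxels[1, , ]
    sqrt(mean((r[support] - disk[support])^2))
  }
  # monotone improvement in the angle-starved regime
  e <- c(rmse_at(45), rmse_at(90), rmse_at(180))
  expect_true(all(diff(e) < 0))
})

test_that("retrieval error decreases monotonically with photon count", {
  geom <- table1_25nm_geometry()
  n <- 128
  x <- seq(-4, 4, length.out = n)
  phase <- 0.1 * outer(exp(-x^2 / 2), exp(-x^2 / 2))
  err <- function(photons) {
    mean(vapply(1:3, function(s) {
      h <- suppressWarnings(
        simulate_hologram_series(phase, geom, rng_seed = s,
                                 photons = photons))
      al <- normalize_and_align(h)
      rec <- ctf_phase_retrieval(al$stack, geom$wavelength_nm,
                                 al$distance_eff_mm, al$pixel_nm)
      rec <- rec - mean(rec[1:6, 1:6])
      sqrt(mean((rec - phase)^2))
    }, 0))
  }
  e <- c(err(1e2), err(1e3), err(1e4))
  expect_true(all(diff(e) < 0))
})
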