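test_that("CNR: identical classes, two-Gaussian fit, scale invariance", {
  v <- array(rep(c(1, 1), each = 500), c(10, 10, 10))
  roi <- array(rep(c(TRUE, FALSE), each = 500), c(10, 10, 10))
  f0 <- cnr(v, roi_a = roi, roi_b = !roi)
  expect_equal(f0$cnr, 0)

  set.seed(21)
  x <- c(rnorm(2e5, 100, 10), rnorm(2e5, 50, 10))
  vol <- array(sample(x), c(40, 100, 100))
  f <- cnr(vol)
  expect_lt(abs(f$cnr - 50 / sqrt(200)), 0.05)
  expect_equal(f$I1, 50, tolerance = 0.02)
  expect_equal(f$I2, 100, tolerance = 0.02)

  f2 <- cnr(vol * 2)
  expect_equal(f2$cnr, f$cnr, tolerance = 1e-3)
  f3 <- cnr(vol * 2 + 1000)
  expect_equal(f3$cnr, f$cnr, tolerance = 1e-3)

  expect_error(cnr(array(1, c(5, 5, 5))), "fit error")
  expect_equal(f$cnr, abs(f$I1 - f$I2) / sqrt(f$sigma1^2 + f$sigma2^2))
})

test_that("bootstrap interval brackets the histogram-mode CNR", {
  set.seed(22)
  x <- c(rnorm(4e4, 100, 10), rnorm(4e4, 50, 10))
  vol <- array(sample(x), c(20, 40, 100))
  f <- cnr(vol, n_boot = 20)
  expect_length(f$interval, 2L)
  expect_true(f$interval[1] <= f$cnr && f$cnr <= f$interval[2])
})

test_that("nMTF resolution: ideal step, Gaussian closed form, scaling law", {
  ideal <- generate_edge_phantom(c(10, 10, 64), blur_sigma = 0,
                                 contrast = 0.3, spacing = 100)
  r0 <- nmtf_resolution(ideal)
  expect_true(r0$at_band_edge)
  expect_equal(r0$resolution_nm, 100)

  blurred <- generate_edge_phantom(c(10, 10, 128), blur_sigma = 2,
                                   contrast = 0.3, spacing = 100)
  r2 <- nmtf_resolution(blurred)
  f10 <- sqrt(log(10)) / (sqrt(2) * pi * 200) # sigma = 2 voxels = 200 nm
  expect_lt(abs(r2$resolution_nm - 1 / (2 * f10)) / (1 / (2 * f10)), 0.1)
  expect_false(r2$at_band_edge)

  blurred4 <- generate_edge_phantom(c(10, 10, 128), blur_sigma = 4,
                                    contrast = 0.3, spacing = 100)
  r4 <- nmtf_resolution(blurred4)
  expect_lt(abs(r4$resolution_nm / r2$resolution_nm - 2), 0.2)

  # median over slices suppresses an impulse artefact in the profile
  noisy <- blurred
  noisy$voxels[5, , ] <- noisy$voxels[5, , ] + 0.5
  rmed <- nmtf_resolution(noisy, median_slices = 9)
  expect_lt(abs(rmed$resolution_nm - r2$resolution_nm) / r2$resolution_nm,
            0.1)
})

test_that("binning never improves the reported nMTF resolution", {
  edge <- generate_edge_phantom(c(12, 12, 128), blur_sigma = 2,
                                contrast = 0.3, spacing = 100)
  r1 <- nmtf_resolution(edge)
  b <- bin_volume(edge, 2)
  b$edge <- list(axis = 3, position = edge$edge$position %/% 2)
  r2 <- nmtf_resolution(b)
  expect_gte(r2$resolution_nm, r1$resolution_nm - 1e-9)
})

test_that("sensitivity: definition, undefined case, permutation invariance", {
  d <- c(30, 60, 60)
  truth <- array(0L, d)
  det <- array(0L, d)
  k <- 0L
  for (zy in seq(5, 45, by = 10)) { # 10 well-separated boxes
    for (rep in 0:1) {
      k <- k + 1L
      y <- zy + 1; x <- 5 + rep * 30 + 1
      truth[8:14, y:(y + 6), x:(x + 6)] <- (k - 1L) * 10L + 1L
      det[8:14, y:(y + 6), x:(x + 6)] <- k
    }
  }
  tv <- volume3d(truth); dv <- volume3d(det)
  s <- sensitivity(dv, tv)
  expect_equal(s$S, 1)
  expect_equal(s$TP, 10L)

  # 9 correct of 10 detected: move one detection into the background
  det9 <- det
  det9[det9 == 4L] <- 0L
  det9[20:26, 40:46, 40:46] <- 4L
  s9 <- sensitivity(volume3d(det9), tv)
  expect_equal(s9$S, 0.9)
  expect_equal(s9$truth_found, 9L)

  # permuting detection labels changes nothing
  perm <- sample(10)
  detp <- array(0L, d)
  detp[det9 > 0L] <- perm[det9[det9 > 0L]]
  expect_equal(sensitivity(volume3d(detp), tv)$S, 0.9)

  expect_message(s0 <- sensitivity(volume3d(array(0L, d)), tv), "undefined")
  expect_true(is.na(s0$S))
})

test_that("ellipse curvature: circle, direct axes, rendered ellipse", {
  circ <- disk_mask(64, c(32.5, 32.5), 20)
  rc <- ellipse_curvature(circ, spacing = 1)
  expect_equal(rc$R, 20, tolerance = 0.03)

  expect_equal(ellipse_curvature(c(4, 2))$R, 8)
  expect_error(ellipse_curvature(c(4, 0)), "degenerate")

  # soma-scale ellipse: 2a = 50 um, 2b = 32.9 um at 0.5 um voxels
  n <- 128
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  mask <- ((yy - 64.5) / 50)^2 + ((xx - 64.5) / 32.9)^2 <= 1
  re <- ellipse_curvature(mask, spacing = 0.5)
  expect_lt(abs(re$R - 38) / 38, 0.05)
  expect_equal(re$a, 25, tolerance = 0.02)
})

test_that("translation registration: identity, integer and subvoxel shifts", {
  set.seed(31)
  base <- nanoholo:::gaussian_filter3(array(rnorm(32^3), c(32, 32, 32)), 2)
  r0 <- translation_register(base, base)
  expect_equal(r0$offset, c(0, 0, 0))
  expect_false(r0$low_confidence)

  shifted <- roll3(base, c(3, -2, 5))
  r <- translation_register(base, shifted)
  expect_equal(r$offset, c(3, -2, 5), tolerance = 0.1)

  # subvoxel shift of a smooth blob, constructed analytically
  g <- function(dz) {
    co <- expand.grid(z = 1:32, y = 1:32, x = 1:32)
    array(exp(-((co$z - 16 - dz)^2 + (co$y - 16)^2 + (co$x - 16)^2) / 18),
          c(32, 32, 32))
  }
  rs <- translation_register(g(0), g(0.4))
  expect_lt(abs(rs$offset[1] - 0.4), 0.25)
  expect_equal(rs$offset[2:3], c(0, 0), tolerance = 0.25)
})

test_that("median over slices: identity, constants, impulse removal", {
  set.seed(41)
  v <- volume3d(array(rnorm(8 * 6 * 6), c(8, 6, 6)))
  expect_equal(median_over_slices(v, 1)$voxels, v$voxels)
  cv <- volume3d(array(2, c(8, 6, 6)))
  expect_equal(median_over_slices(cv, 3)$voxels, cv$voxels)

  imp <- volume3d(array(0, c(9, 5, 5)))
  imp$voxels[5, 3, 3] <- 7
  expect_true(all(median_over_slices(imp, 3)$voxels == 0))
  expect_error(median_over_slices(imp, 11), "slice count")
})

test_that("H&E colour transfer: identity, exact lookup, monotonicity", {
  # a histology image that is itself grayscale transfers as identity
  g <- matrix(rep(seq(30, 220, length.out = 64), 64), 64)
  hrgb <- array(rep(g, 3), c(64, 64, 3))
  out <- hne_color_transfer(g, hrgb, rgb_to_gray(hrgb))
  expect_lt(max(abs(out[, , 1] - g)), 1.6) # identity up to integer binning

  # two-colour histology: gray 50 <-> pink, gray 200 <-> purple
  pink <- c(238, 160, 190); purple <- c(94, 44, 130)
  hg <- matrix(rep(c(50, 200), each = 32), 8)
  hr <- array(0, c(8, 8, 3))
  for (k in 1:3) hr[, , k] <- ifelse(hg == 50, pink[k], purple[k])
  tom <- matrix(c(50, 200, 50, 200), 2)
  out2 <- hne_color_transfer(tom, hr, hg)
  expect_equal(out2[1, 1, ], pink)
  expect_equal(out2[2, 2, ], purple)

  # monotone lookup gives monotone output luminance
  his <- synthesize_hne_image(seed = 3)
  ramp <- matrix(seq(0, 255, length.out = 100), 1)
  lum <- rgb_to_gray(suppressWarnings(
    hne_color_transfer(ramp, his$rgb, his$gray)))
  # luminance may plateau where the lookup clamps, but must not oscillate
  dl <- diff(as.vector(lum))
  expect_true(all(dl >= -1e-9) || all(dl <= 1e-9))
})

test_that("metric reports serialize and reload losslessly", {
  rep0 <- list(cnr = list(I1 = 0.4512345678901, I2 = 0.6098765432109,
                          sigma1 = 0.05, sigma2 = 0.049, cnr = 2.26615),
               resolution_nm = 292.8341, sensitivity = 0.9,
               offsets = c(3, -2, 5))
  path <- tempfile(fileext = ".json")
  write_metrics_report(rep0, path)
  back <- read_metrics_report(path)
  expect_equal(back$cnr$I1, rep0$cnr$I1, tolerance = 1e-12)
  expect_equal(back$resolution_nm, rep0$resolution_nm, tolerance = 1e-12)
  expect_equal(back$offsets, rep0$offsets)
})
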