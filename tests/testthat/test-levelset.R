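test_that("sfm_evolve: zero iterations return the initialization exactly", {
  s <- sphere_image()
  init <- ball_mask(48, c(24, 24, 24), 9)
  out <- sfm_evolve(s$img, init, 0, 0.01)
  expect_identical(out != 0, init)
  expect_error(sfm_evolve(s$img, array(0, dim(s$img)), 10, 0.01), "empty")
})

test_that("sfm_evolve recovers a noisy sphere from an eroded seed", {
  s <- sphere_image(contrast = 0.25, noise = 0.05) # contrast/noise = 5
  init <- ball_mask(48, rep(24.5, 3), 9)
  out <- sfm_evolve(s$img, init, 200, 0.01)
  dice <- 2 * sum(out & s$truth) / (sum(out) + sum(s$truth))
  expect_gt(dice, 0.95)
})

test_that("strong smoothing removes a thin spurious filament", {
  n <- 48
  truth <- ball_mask(n, rep(24.5, 3), 10)
  fil <- array(FALSE, dim(truth))
  fil[24:25, 24:25, 35:46] <- TRUE # 2-voxel-wide appendage
  set.seed(2)
  img <- 0.45 + 0.25 * (truth | fil) + array(rnorm(n^3, sd = 0.03), dim(truth))
  out <- sfm_evolve(img, truth | fil, 200, 1)
  far <- fil & !ball_mask(n, rep(24.5, 3), 13)
  expect_lt(sum(out[far]) / sum(far), 0.1)
  # the sphere body itself survives
  expect_gt(sum(out & truth) / sum(truth), 0.8)
})

test_that("updates stay within the sparse band around the zero level set", {
  s <- sphere_image(n = 40, radius = 10, noise = 0.05)
  init <- ball_mask(40, rep(20.5, 3), 8)
  phi0 <- sfm_evolve(s$img, init, 0, 0.01, details = TRUE)$phi
  phi1 <- sfm_evolve(s$img, init, 1, 0.01, details = TRUE)$phi
  changed <- phi0 != phi1
  # voxels within Chebyshev distance 2 of the initial boundary
  boundary <- abs(phi0) <= 2
  grown <- boundary
  for (sft in 1:2) {
    d <- dim(boundary)
    g <- grown
    for (ax in 1:3) {
      idx_lo <- lapply(d, seq_len); idx_lo[[ax]] <- c(1, seq_len(d[ax] - 1))
      idx_hi <- lapply(d, seq_len); idx_hi[[ax]] <- c(seq_len(d[ax] - 1) + 1, d[ax])
      g <- g | grown[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]] |
        grown[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]]
    }
    grown <- g
  }
  expect_true(all(grown[changed]))
  expect_lt(mean(changed), 0.2) # the touched set is sparse
})

test_that("pure curvature flow shrinks a sphere monotonically", {
  n <- 40
  img <- array(0.5, c(n, n, n)) # constant image: zero data force
  init <- ball_mask(n, rep(20.5, 3), 12)
  vols <- vapply(c(0, 10, 25, 50), function(it)
    sum(sfm_evolve(img, init, it, 1)), 0)
  expect_true(all(diff(vols) <= 0))
  expect_lt(vols[4], vols[1])
})

test_that("higher smoothness never increases the isoperimetric roughness", {
  # surface-to-volume in the shape sense: SA / V^(2/3) is scale-free, so the
  # comparison is not confounded by the volume loss that smoothing causes
  s <- sphere_image(n = 40, radius = 11, noise = 0.06, seed = 4)
  init <- ball_mask(40, rep(20.5, 3), 8)
  roughness <- function(zeta) {
    m <- sfm_evolve(s$img, init, 150, zeta)
    d <- dim(m)
    faces <- 0
    for (ax in 1:3) {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- idx[[ax]][-d[ax]]
      a <- m[idx[[1]], idx[[2]], idx[[3]]]
      idx[[ax]] <- idx[[ax]] + 1
      b <- m[idx[[1]], idx[[2]], idx[[3]]]
      faces <- faces + sum(a != b)
    }
    faces / sum(m)^(2 / 3)
  }
  # between two already-smooth contours the difference sits at the voxel
  # quantization level, so each smoothed run is compared to the rough
  # zeta = 0 baseline with a 1% quantization allowance
  r0 <- roughness(0)
  for (z in c(0.1, 0.5, 1)) expect_lte(roughness(z), r0 * 1.01)
  expect_lt(roughness(1), 0.9 * r0) # and the smoothing effect is real
})

test_that("automated segmentation: empty phantom yields zero objects", {
  sp <- phantom_spec(shape = c(80, 80, 80), rng_seed = 3)
  ph <- generate_tissue_phantom(sp)
  seg <- suppressWarnings(
    segment_automated(ph$intensity, frangi_params(), sfm_params()))
  expect_equal(nrow(seg$objects), 0L)
})

test_that("benchmark phantom: >= 9 of 10 cells recovered with Dice > 0.7", {
  b <- benchmark_segmentation(1)
  recovered <- sum(b$dice > 0.7)
  expect_gte(recovered, 9)
  expect_gte(b$sens$S, 0.9)
})

test_that("segmentation is deterministic", {
  sp <- phantom_spec(shape = c(64, 64, 64),
                     cells = list(cell_spec(center = c(31, 33, 30),
                                            radii = c(10, 10, 11))),
                     rng_seed = 8)
  ph <- generate_tissue_phantom(sp)
  fp <- frangi_params(radius_min = 8, radius_max = 12,
                      min_object_voxels = 1000, exclude_border = FALSE)
  sp2 <- sfm_params(n_iterations_2d = 200, n_iterations_3d = 30)
  a <- segment_automated(ph$intensity, fp, sp2)
  b <- segment_automated(ph$intensity, fp, sp2)
  expect_identical(a$labels$voxels, b$labels$voxels)
  expect_equal(nrow(a$objects), 1L)
})

test_that("a 200-voxel object is removed by the final size filter", {
  sp <- phantom_spec(shape = c(48, 48, 48),
                     cells = list(cell_spec(center = c(23, 24, 23),
                                            radii = c(3.6, 3.6, 3.65),
                                            nucleolus_radius = 1,
                                            envelope_thickness = 1)),
                     psf_sigma = 0.5, rng_seed = 5)
  ph <- generate_tissue_phantom(sp)
  expect_lt(sum(compartment_mask(ph$labels, compartment = "soma")), 300)
  fp <- frangi_params(radius_min = 3, radius_max = 5, radius_step = 1,
                      min_object_voxels = 0, exclude_border = FALSE)
  spp <- sfm_params(n_iterations_2d = 200, n_iterations_3d = 30)
  seg <- suppressWarnings(segment_automated(ph$intensity, fp, spp))
  expect_equal(nrow(seg$objects), 0L)
  # the same run with a lenient final filter does find the object
  spp2 <- sfm_params(n_iterations_2d = 200, n_iterations_3d = 30,
                     min_final_voxels = 50)
  seg2 <- suppressWarnings(segment_automated(ph$intensity, fp, spp2))
  expect_gte(nrow(seg2$objects), 1L)
})

test_that("semi-automated: one-slice object stays confined to its slice", {
  n <- 30
  img <- array(0.4, c(n, n, n))
  sq <- matrix(FALSE, n, n); sq[11:20, 11:20] <- TRUE
  img[15, , ][sq] <- 0.8
  sp <- sfm_params(n_iterations_2d = 300, n_iterations_3d = 0,
                   min_final_voxels = 0)
  seg <- segment_semiautomated(volume3d(img), 14L, sq, sp)
  lab <- seg$labels$voxels
  expect_gt(sum(lab[15, , ] != 0), 0)
  expect_equal(sum(lab[-15, , ] != 0), 0)
})

test_that("semi-automated: sphere seeded at the equator is fully recovered", {
  n <- 56
  truth <- ball_mask(n, rep(28.5, 3), 14)
  set.seed(6)
  img <- 0.45 + 0.25 * truth + array(rnorm(n^3, sd = 0.04), dim(truth))
  seed <- disk_mask(n, c(28.5, 28.5), 10)
  sp <- sfm_params(n_iterations_2d = 300, n_iterations_3d = 30)
  seg <- segment_semiautomated(volume3d(img), 28L, seed, sp)
  vol <- sum(seg$labels$voxels != 0)
  expect_lt(abs(vol - 4 / 3 * pi * 14^3) / (4 / 3 * pi * 14^3), 0.1)
  expect_error(segment_semiautomated(volume3d(img), 28L,
                                     matrix(FALSE, n, n), sp), "empty")
})

test_that("semi-automated: two seeds on two cells stay separate", {
  n <- 64
  t1 <- ball_mask(n, c(20, 20, 20), 10)
  t2 <- ball_mask(n, c(20, 44, 44), 10)
  set.seed(7)
  img <- 0.45 + 0.25 * (t1 | t2) + array(rnorm(n^3, sd = 0.04), dim(t1))
  seed <- disk_mask(n, c(20, 20), 7) | disk_mask(n, c(44, 44), 7)
  sp <- sfm_params(n_iterations_2d = 300, n_iterations_3d = 30)
  seg <- segment_semiautomated(volume3d(img), 19L, seed, sp)
  expect_equal(nrow(seg$objects), 2L)
  lab <- seg$labels$voxels
  expect_gt(sum(lab != 0 & t1), 0.5 * sum(t1))
  expect_gt(sum(lab != 0 & t2), 0.5 * sum(t2))
  # no single label spans both cells
  for (k in seq_len(max(lab)))
    expect_true(sum(lab == k & t1) == 0 || sum(lab == k & t2) == 0)
})

test_that("region growing: exact constant region, nested phantom, full range", {
  img <- array(0.3, c(20, 20, 20))
  img[5:10, 5:10, 5:10] <- 0.9
  seg <- region_growing(volume3d(img), matrix(c(6, 6, 6), 1), tolerance = 0)
  expect_equal(sum(seg$labels$voxels == 1L), 6^3)
  expect_equal(unname(which(seg$labels$voxels == 1L, arr.ind = TRUE)[1, ]),
               c(5, 5, 5))

  segall <- region_growing(volume3d(img), matrix(c(0, 0, 0), 1), tolerance = 2)
  expect_true(all(segall$labels$voxels == 1L))

  sp <- phantom_spec(shape = c(48, 48, 48),
                     cells = list(cell_spec(center = c(23.5, 23.5, 23.5),
                                            radii = c(14, 14, 14))),
                     psf_sigma = 0, noise_sigma = 0,
                     neuropil_texture_sigma = 0)
  ph <- generate_tissue_phantom(sp)
  segn <- region_growing(ph$intensity, matrix(c(23, 23, 23), 1),
                         tolerance = 0.05)
  truth_n <- sum(compartment_mask(ph$labels, compartment = "nucleolus"))
  got <- sum(segn$labels$voxels == 1L)
  expect_lt(abs(got - truth_n) / truth_n, 0.02)

  bad <- volume3d(array(c(NaN, rep(1, 7)), c(2, 2, 2)))
  expect_error(region_growing(bad, matrix(c(0, 0, 0), 1), 0.1), "NaN")
})
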