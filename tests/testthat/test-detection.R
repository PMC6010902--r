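test_that("Hessian eigenvalues: constants, blobs, tubes", {
  const <- volume3d(array(5, c(32, 32, 32)))
  ev <- hessian_eigenvalues(const, 2)
  expect_lt(max(vapply(ev, function(e) max(abs(e$voxels)), 0)), 1e-12)

  # bright Gaussian blob, Hessian at the matching scale: at the centre all
  # three eigenvalues equal -A (s^2/(s^2+sigma^2))^{3/2} sigma^2/(s^2+sigma^2)
  n <- 49; s <- 4; A <- 1
  x <- seq_len(n) - 25
  g1 <- exp(-x^2 / (2 * s^2))
  blob <- A * outer(outer(g1, g1), g1)
  dim(blob) <- c(n, n, n)
  ev <- hessian_eigenvalues(volume3d(blob), s)
  lam <- vapply(ev, function(e) e$voxels[25, 25, 25], 0)
  lam_expected <- -A * (s^2 / (2 * s^2))^(3 / 2) * s^2 / (2 * s^2)
  expect_true(all(lam < 0))
  expect_equal(unname(lam), rep(lam_expected, 3), tolerance = 0.03)

  # bright straight tube along z: |l1| << |l2| ~ |l3| on the axis
  tube <- array(rep(outer(g1, g1), each = n), c(n, n, n))
  evt <- hessian_eigenvalues(volume3d(tube), s)
  l <- vapply(evt, function(e) e$voxels[25, 25, 25], 0)
  expect_lt(abs(l[1]), 0.05 * abs(l[2]))
  expect_lt(abs(l[2] - l[3]), 0.05 * abs(l[3]))
  expect_error(hessian_eigenvalues(volume3d(array(0, c(8, 8, 8))), 5),
               "kernel support")
  expect_error(hessian_eigenvalues(const, 0), "parameter error")
})

test_that("objectness response: constants, noise suppression, bright shell", {
  p <- frangi_params()
  const <- volume3d(array(3, c(80, 80, 80)))
  expect_lt(max(frangi_response(const, p)$voxels), 1e-12)

  # noise with std far below gamma is suppressed by the structureness term
  set.seed(11)
  noisy <- volume3d(array(100 + rnorm(80^3, sd = 5), c(80, 80, 80)))
  pn <- frangi_params(gamma_scale = "none") # gamma = 60 gray units verbatim
  rn <- frangi_response(noisy, pn)
  expect_lt(max(rn$voxels), 0.01)

  # bright shell of radius 20: suprathreshold connected component on it
  n <- 96
  co <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  r2 <- (co$z - 48.5)^2 + (co$y - 48.5)^2 + (co$x - 48.5)^2
  shell <- array(r2 >= 18.5^2 & r2 <= 21.5^2, c(n, n, n))
  img <- volume3d(array(0.45 + 0.3 * shell, c(n, n, n)))
  resp <- frangi_response(img, p)
  expect_gt(max(resp$voxels[shell]), p$binarize_threshold)
  lab <- nanoholo:::cpp_label_components(
    resp$voxels >= p$binarize_threshold, as.integer(dim(resp$voxels)), 26L)
  onshell <- unique(lab[which(shell)])
  onshell <- setdiff(onshell, 0L)
  expect_gte(length(onshell), 1L)
  expect_gt(max(tabulate(lab[lab > 0])), 1000)
})

test_that("response is invariant under volume-wide intensity offsets", {
  set.seed(5)
  base <- array(0.5 + 0.1 * rnorm(40^3), c(40, 40, 40))
  base <- nanoholo:::gaussian_filter3(base, 2)
  p <- frangi_params(radius_min = 6, radius_max = 10, radius_step = 2)
  r1 <- frangi_response(volume3d(base), p)
  r2 <- frangi_response(volume3d(base + 100), p)
  expect_equal(r1$voxels, r2$voxels, tolerance = 1e-8)
})

test_that("initialization mask applies threshold, size and border filters", {
  p <- frangi_params()
  d <- c(90, 90, 90)
  resp <- array(0, d)
  expect_warning(make_initialization_mask(volume3d(resp), p), "empty")

  # three components: 25,200 / 10,164 / 25,200-but-border-touching
  resp[10:39, 10:39, 10:37] <- 0.5          # 30*30*28 = 25200, kept
  resp[50:71, 50:71, 50:70] <- 0.5          # 22*22*21 = 10164, too small
  resp[60:89, 1:30, 10:37] <- 0.5           # touches the y = 0 face
  init <- make_initialization_mask(volume3d(resp), p)
  expect_equal(sum(init$objects$kept), 1L)
  expect_equal(max(init$mask$voxels), 1L)
  expect_equal(sum(init$mask$voxels == 1L), 25200)
  expect_equal(nrow(init$objects), 3L)

  # threshold 1.0 over a response < 1 keeps nothing
  p1 <- frangi_params(binarize_threshold = 1)
  expect_warning(got <- make_initialization_mask(volume3d(resp), p1),
                 "empty")
  expect_equal(max(got$mask$voxels), 0L)
})

test_that("raising the size filter never increases the survivor count", {
  set.seed(9)
  field <- nanoholo:::gaussian_filter3(array(rnorm(60^3), c(60, 60, 60)), 4)
  resp <- volume3d(array(pmin(pmax(field * 3, 0), 1), c(60, 60, 60)))
  sizes <- c(0, 50, 200, 1000, 5000)
  counts <- vapply(sizes, function(ms) {
    p <- frangi_params(binarize_threshold = 0.2, min_object_voxels = ms,
                       exclude_border = FALSE)
    sum(suppressWarnings(make_initialization_mask(resp, p))$objects$kept)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})
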