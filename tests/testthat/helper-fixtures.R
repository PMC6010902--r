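# Fixtures are generated in code; the heavyweight benchmark segmentations
# (one ~200^3 phantom per seed) are cached across test files.

.nh_cache <- new.env(parent = emptyenv())

# full two-step segmentation of the benchmark phantom for one seed,
# with sensitivity and per-true-cell Dice attached
benchmark_segmentation <- function(seed) {
  key <- paste0("seg", seed)
  if (!is.null(.nh_cache[[key]])) return(.nh_cache[[key]])
  spec <- benchmark_phantom_spec(seed)
  ph <- generate_tissue_phantom(spec)
  seg <- segment_automated(ph$intensity, frangi_params(), sfm_params())
  sens <- suppressMessages(sensitivity(seg, ph$labels))
  lab <- seg$labels$voxels
  dice <- vapply(seq_along(spec$cells), function(i) {
    tm <- compartment_mask(ph$labels, cell = i, compartment = "soma")
    if (max(lab) == 0L) return(0)
    max(vapply(seq_len(max(lab)), function(k) {
      dm <- lab == k
      2 * sum(dm & tm) / (sum(dm) + sum(tm))
    }, 0))
  }, 0)
  out <- list(phantom = ph, seg = seg, sens = sens, dice = dice)
  .nh_cache[[key]] <- out
  out
}

# solid ball mask in an n^3 array
ball_mask <- function(n, center, radius) {
  co <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  array((co$z - center[1])^2 + (co$y - center[2])^2 +
          (co$x - center[3])^2 <= radius^2, c(n, n, n))
}

disk_mask <- function(n, center, radius) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

# noisy bright-sphere test image
sphere_image <- function(n = 48, radius = 14, contrast = 0.25,
                         noise = 0.05, seed = 1) {
  truth <- ball_mask(n, rep((n + 1) / 2, 3), radius)
  set.seed(seed)
  img <- 0.45 + contrast * truth + array(rnorm(n^3, sd = noise), dim(truth))
  list(img = img, truth = truth)
}

# circular shift of a 3-D array (for registration oracles)
roll3 <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) ((seq_len(d[k]) - 1 - s[k]) %% d[k]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}
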