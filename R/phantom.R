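#' Specification of a single synthetic cell
#'
#' Describes an ellipsoidal neuron soma with nested subcellular
#' compartments: a nucleus (lower electron density than the cytoplasm), a
#' thin bright nuclear envelope forming the outer shell of the nucleus, and
#' a small dense nucleolus at the cell centre.  Gray values are dimensionless
#' electron-density-like units; the package default ordering is
#' nucleus < neuropil < cytoplasm < envelope < nucleolus.
#'
#' @param center 0-based voxel coordinates `(z, y, x)` of the cell centre, or
#'   `NULL` to auto-place the cell without overlap when the phantom is
#'   generated.
#' @param radii three ellipsoid semi-axes in voxels `(z, y, x)`.
#' @param orientation 3x3 rotation matrix giving the ellipsoid axes
#'   (default identity).
#' @param soma_density,nucleus_density,envelope_density,nucleolus_density
#'   gray values of the compartments.
#' @param envelope_thickness nuclear-envelope thickness in voxels (>= 1).
#' @param nucleolus_radius nucleolus radius in voxels.
#' @param nucleus_scale nucleus semi-axes as a fraction of the soma semi-axes.
#' @param cell_class one of `"pyramidal"`, `"purkinje"`, `"granule"`,
#'   `"stellate"`; informational.
#' @return A `CellSpec` object.
#' @export
cell_spec <- function(center = NULL, radii = c(20, 20, 20),
                      orientation = diag(3),
                      soma_density = 0.60, nucleus_density = 0.35,
                      envelope_density = 0.75, nucleolus_density = 0.90,
                      envelope_thickness = 2, nucleolus_radius = 3.5,
                      nucleus_scale = 0.55,
                      cell_class = c("pyramidal", "purkinje", "granule",
                                     "stellate")) {
  cell_class <- match.arg(cell_class)
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0))
    stop("`radii` must be three positive semi-axes (voxels)", call. = FALSE)
  if (!is.null(center) && (length(center) != 3L || any(!is.finite(center))))
    stop("`center` must be NULL or a length-3 coordinate", call. = FALSE)
  if (envelope_thickness < 1)
    stop("`envelope_thickness` must be >= 1 voxel", call. = FALSE)
  dens <- c(soma_density, nucleus_density, envelope_density, nucleolus_density)
  if (any(!is.finite(dens))) stop("densities must be finite", call. = FALSE)
  if (nucleus_scale <= 0 || nucleus_scale >= 1)
    stop("`nucleus_scale` must be in (0, 1) so the nucleus nests in the soma",
         call. = FALSE)
  if (nucleolus_radius >= nucleus_scale * min(radii))
    stop("nucleolus must be contained in the nucleus", call. = FALSE)
  if (!is.matrix(orientation) || !all(dim(orientation) == c(3, 3)))
    stop("`orientation` must be a 3x3 rotation matrix", call. = FALSE)
  structure(list(center = center, radii = as.numeric(radii),
                 orientation = orientation,
                 soma_density = soma_density, nucleus_density = nucleus_density,
                 envelope_density = envelope_density,
                 nucleolus_density = nucleolus_density,
                 envelope_thickness = envelope_thickness,
                 nucleolus_radius = nucleolus_radius,
                 nucleus_scale = nucleus_scale, cell_class = cell_class),
            class = "CellSpec")
}

#' Specification of a synthetic tissue phantom
#'
#' The phantom emulates paraffin-embedded brain tissue as reconstructed by
#' phase tomography: a neuropil background carrying a low-pass-filtered
#' Gaussian texture (cell boundaries in such data are detectable through the
#' neuropil/cell contrast, not through membranes), ellipsoidal somata with
#' nested compartments, then degradation by a Gaussian point-spread function
#' and additive Gaussian noise.  Photon (Poisson) noise belongs to the
#' holographic forward model, not here.
#'
#' @param shape volume dimensions `(nz, ny, nx)` in voxels.
#' @param spacing voxel size in nm.
#' @param neuropil_density background gray value.
#' @param neuropil_texture_sigma correlation length (voxels) of the background
#'   texture; 0 disables the texture.
#' @param neuropil_texture_amplitude standard deviation of the texture in
#'   gray units.
#' @param cells list of [cell_spec()] objects.
#' @param psf_sigma Gaussian point-spread sigma in voxels (0 = none).
#' @param noise_sigma additive Gaussian noise sigma in gray units.
#' @param rng_seed integer seed; identical seeds give bit-identical phantoms.
#' @return A `PhantomSpec` object.
#' @export
phantom_spec <- function(shape, spacing = 100, neuropil_density = 0.45,
                         neuropil_texture_sigma = 3,
                         neuropil_texture_amplitude = 0.02,
                         cells = list(), psf_sigma = 1, noise_sigma = 0.05,
                         rng_seed = 1L) {
  if (length(shape) != 3L || any(shape < 1))
    stop("`shape` must be three positive dimensions", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  if (psf_sigma < 0 || noise_sigma < 0)
    stop("`psf_sigma` and `noise_sigma` must be >= 0", call. = FALSE)
  if (neuropil_texture_sigma < 0 || neuropil_texture_amplitude < 0)
    stop("texture parameters must be >= 0", call. = FALSE)
  if (!all(vapply(cells, inherits, TRUE, "CellSpec")))
    stop("`cells` must be a list of CellSpec objects", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 neuropil_density = neuropil_density,
                 neuropil_texture_sigma = neuropil_texture_sigma,
                 neuropil_texture_amplitude = neuropil_texture_amplitude,
                 cells = cells, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
            class = "PhantomSpec")
}

#' Random cell population for a phantom
#'
#' Draws `n` cells with semi-axes uniform in `radius_range` (the soma size
#' window the detection stage is tuned to) and auto-placed centres.
#'
#' @param n number of cells.
#' @param radius_range semi-axis range in voxels.
#' @param cell_class passed to [cell_spec()].
#' @return list of `CellSpec` (centres unset; placement happens at
#'   generation time under the phantom seed).
#' @export
random_cells <- function(n, radius_range = c(15, 25),
                         cell_class = "pyramidal") {
  lapply(seq_len(n), function(i)
    cell_spec(center = NULL, radii = rep(mean(radius_range), 3),
              cell_class = cell_class))
}

# compartment codes within a cell's label decade
COMP_CODES <- c(soma = 1L, nucleus = 2L, envelope = 3L, nucleolus = 4L)

#' Masks for cells and compartments in a phantom label volume
#'
#' Phantom labels encode cell `i` (1-based) compartment `c` as
#' `(i - 1) * 10 + c` with compartment codes 1 = cytoplasm, 2 = nucleus
#' content, 3 = nuclear envelope, 4 = nucleolus; background is 0.  The
#' nesting `nucleolus %in% nucleus %in% soma` holds voxel-wise: the soma mask
#' is any compartment, the nucleus mask is codes 2-4 (the envelope is the
#' nucleus' outer shell).
#'
#' @param labels `Volume3D` of integer labels (or plain array).
#' @param cell 1-based cell index, or `NULL` for all cells.
#' @param compartment `"soma"`, `"nucleus"`, `"envelope"` or `"nucleolus"`.
#' @return logical array.
#' @export
compartment_mask <- function(labels, cell = NULL,
                             compartment = c("soma", "nucleus", "envelope",
                                             "nucleolus")) {
  compartment <- match.arg(compartment)
  lab <- if (is_volume3d(labels)) labels$voxels else labels
  code <- lab %% 10L
  code[lab == 0L] <- 0L
  idx <- (lab - 1L) %/% 10L + 1L
  sel <- switch(compartment,
                soma = code >= 1L,
                nucleus = code >= 2L,
                envelope = code == 3L,
                nucleolus = code == 4L)
  if (!is.null(cell)) sel <- sel & (idx == cell) & code >= 1L
  array(sel, dim(lab))
}

# rotated normalized ellipsoid quadratic form over a coordinate block
ellipsoid_q <- function(zz, yy, xx, center, radii, rot) {
  dz <- zz - center[1]; dy <- yy - center[2]; dx <- xx - center[3]
  u <- rot[1, 1] * dz + rot[1, 2] * dy + rot[1, 3] * dx
  v <- rot[2, 1] * dz + rot[2, 2] * dy + rot[2, 3] * dx
  w <- rot[3, 1] * dz + rot[3, 2] * dy + rot[3, 3] * dx
  (u / radii[1])^2 + (v / radii[2])^2 + (w / radii[3])^2
}

#' Generate a synthetic tissue volume with ground-truth labels
#'
#' Renders the neuropil background, paints each cell's compartments at the
#' densities in its [cell_spec()], then degrades the intensity volume with
#' the Gaussian point-spread function and additive noise.  Labels are taken
#' before degradation and are geometrically congruent with the intensity
#' volume.  All randomness (texture, placement, noise) flows from
#' `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `intensity` (`Volume3D`) and `labels` (integer
#'   `Volume3D`, see [compartment_mask()] for the encoding).
#' @export
generate_tissue_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$shape
  with_seed(spec$rng_seed, {
    vol <- array(spec$neuropil_density, d)
    if (spec$neuropil_texture_sigma > 0 && spec$neuropil_texture_amplitude > 0) {
      tex <- gaussian_filter3(array(stats::rnorm(prod(d)), d),
                              spec$neuropil_texture_sigma)
      vol <- vol + tex * (spec$neuropil_texture_amplitude / stats::sd(tex))
    }
    labels <- array(0L, d)

    cells <- place_cells(spec$cells, d)
    zz <- NULL # coordinate blocks built per cell below
    for (i in seq_along(cells)) {
      cs <- cells[[i]]
      ctr <- cs$center
      rmax <- max(cs$radii)
      lo <- pmax(floor(ctr - rmax - 1), 0)
      hi <- pmin(ceiling(ctr + rmax + 1), d - 1)
      if (any(lo > hi)) next
      iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
      bz <- array(iz, c(length(iz), length(iy), length(ix)))
      by <- array(rep(iy, each = length(iz)), dim(bz))
      bx <- array(rep(ix, each = length(iz) * length(iy)), dim(bz))
      rot <- t(cs$orientation) # world -> ellipsoid axes

      qs <- ellipsoid_q(bz, by, bx, ctr, cs$radii, rot)
      rn <- cs$nucleus_scale * cs$radii
      qn <- ellipsoid_q(bz, by, bx, ctr, rn, rot)
      rinner <- pmax(rn - cs$envelope_thickness, 1e-6)
      qe <- ellipsoid_q(bz, by, bx, ctr, rinner, rot)
      qo <- (bz - ctr[1])^2 + (by - ctr[2])^2 + (bx - ctr[3])^2

      base <- 10L * (i - 1L)
      blockv <- vol[iz + 1, iy + 1, ix + 1, drop = FALSE]
      blockl <- labels[iz + 1, iy + 1, ix + 1, drop = FALSE]
      soma <- qs <= 1
      blockv[soma] <- cs$soma_density
      blockl[soma] <- base + COMP_CODES[["soma"]]
      nuc <- qn <= 1
      blockv[nuc] <- cs$nucleus_density
      blockl[nuc] <- base + COMP_CODES[["nucleus"]]
      env <- nuc & qe > 1
      blockv[env] <- cs$envelope_density
      blockl[env] <- base + COMP_CODES[["envelope"]]
      no <- qo <= cs$nucleolus_radius^2
      blockv[no] <- cs$nucleolus_density
      blockl[no] <- base + COMP_CODES[["nucleolus"]]
      vol[iz + 1, iy + 1, ix + 1] <- blockv
      labels[iz + 1, iy + 1, ix + 1] <- blockl
    }

    if (spec$psf_sigma > 0) vol <- gaussian_filter3(vol, spec$psf_sigma)
    if (spec$noise_sigma > 0)
      vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sigma), d)

    list(intensity = volume3d(vol, spec$spacing),
         labels = volume3d(labels, spec$spacing))
  })
}

# auto-place cells whose center is NULL: rejection sampling keeping at least
# `gap` voxels between ellipsoid bounding spheres and off the volume faces
place_cells <- function(cells, d, gap = 6, max_attempts = 500) {
  placed <- list()
  for (cs in cells) {
    if (is.null(cs$center)) {
      rmax <- max(cs$radii)
      lo <- rmax + 2
      hi <- d - 3 - rmax
      if (any(hi <= lo))
        stop("phantom placement error: cell of radius ", rmax,
             " cannot fit inside the volume", call. = FALSE)
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        ctr <- stats::runif(3, lo, hi)
        sep <- vapply(placed, function(p)
          sqrt(sum((ctr - p$center)^2)) >= (rmax + max(p$radii) + gap), TRUE)
        if (all(sep)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("phantom placement error: auto-placement exhausted after ",
             max_attempts, " attempts", call. = FALSE)
      cs$center <- ctr
    }
    placed <- c(placed, list(cs))
  }
  placed
}

#' Generate a step-edge phantom for resolution estimation
#'
#' Half of the volume (along `edge_axis`) sits at a low level, the other half
#' `contrast` gray units higher; the step is then Gaussian-blurred and noisy.
#' The edge plane location is recorded in the returned object (`$edge`).
#'
#' @param shape volume dimensions `(nz, ny, nx)`.
#' @param blur_sigma Gaussian blur sigma in voxels (>= 0).
#' @param contrast step height in gray units.
#' @param noise_sigma additive Gaussian noise sigma.
#' @param spacing voxel size in nm.
#' @param edge_axis axis (1 = z, 2 = y, 3 = x) perpendicular to which the
#'   edge plane lies.
#' @param rng_seed seed for the noise.
#' @return `Volume3D` with an extra `edge = list(axis, position)` element;
#'   `position` is the 0-based index of the first high voxel.
#' @export
generate_edge_phantom <- function(shape, blur_sigma = 0, contrast = 0.3,
                                  noise_sigma = 0, spacing = 100,
                                  edge_axis = 3, rng_seed = 1L) {
  if (length(shape) != 3L || any(shape < 2))
    stop("`shape` must be three dimensions >= 2", call. = FALSE)
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  pos <- shape[edge_axis] %/% 2
  idx <- seq_len(shape[edge_axis]) - 1L
  prof <- ifelse(idx >= pos, 0.25 + contrast, 0.25)
  vol <- array(0, shape)
  perm <- switch(edge_axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  vol <- aperm(array(prof, shape[perm]), order(perm))
  if (blur_sigma > 0) vol <- gaussian_filter3(vol, blur_sigma)
  if (noise_sigma > 0)
    vol <- with_seed(rng_seed,
                     vol + array(stats::rnorm(prod(shape), sd = noise_sigma),
                                 shape))
  out <- volume3d(vol, spacing)
  out$edge <- list(axis = edge_axis, position = as.integer(pos))
  out
}

#' Block-mean binning of a volume
#'
#' Downsamples by averaging `factor^3` blocks, multiplying the voxel spacing
#' by `factor` (the classic trade of spatial resolution for density
#' contrast).  Dimensions that are not multiples of `factor` are truncated;
#' the number of voxels dropped per axis is recorded in the result's
#' `truncated` element.  Mean intensity over the retained region is conserved
#' to machine precision.
#'
#' @param v `Volume3D`.
#' @param factor positive integer binning factor.
#' @return binned `Volume3D`.
#' @export
bin_volume <- function(v, factor) {
  stopifnot(is_volume3d(v))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1)
    stop("`factor` must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(v)
  d <- dim(v$voxels)
  keep <- (d %/% factor) * factor
  if (any(keep < factor)) stop("volume too small for this factor", call. = FALSE)
  a <- v$voxels[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                drop = FALSE]
  # three passes of block sums, rotating the leading axis
  for (k in 1:3) {
    dd <- dim(a)
    a <- colSums(array(a, c(factor, dd[1] %/% factor, dd[2], dd[3])))
    a <- aperm(a, c(2, 3, 1))
  }
  out <- volume3d(a / factor^3, spacing = v$spacing * factor,
                  origin = v$origin)
  out$truncated <- d - keep
  out
}

#' Luminance grayscale of an RGB image
#'
#' Fixed Rec. 601 luminance: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb array `h x w x 3` with values in 0..255.
#' @return matrix `h x w` of gray values.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  rgb[, , 1] * 0.299 + rgb[, , 2] * 0.587 + rgb[, , 3] * 0.114
}

#' Synthesize an H&E-like histology image
#'
#' Produces a 2-D RGB image with the pink/purple palette of a hematoxylin and
#' eosin stained section: an eosin-textured pink background with scattered
#' dark-purple nuclear profiles, plus the paired grayscale obtained with the
#' fixed luminance formula of [rgb_to_gray()].  Used as the reference pair for
#' histology colour-transfer tests; it emulates palette and histogram shape,
#' not real tissue morphology.
#'
#' @param seed integer seed; identical seeds give identical images.
#' @param shape image height and width in pixels.
#' @param n_nuclei number of nuclear profiles.
#' @return list with `rgb` (`h x w x 3`, 0..255) and `gray` (`h x w`).
#' @export
synthesize_hne_image <- function(seed = 1L, shape = c(192, 192),
                                 n_nuclei = 40) {
  with_seed(seed, {
    h <- shape[1]; w <- shape[2]
    tex <- matrix(stats::rnorm(h * w), h, w)
    tex <- array(tex, c(h, w, 1))
    tex <- gaussian_filter3(array(tex, c(h, w, 1)), 4)[, , 1]
    tex <- (tex - min(tex)) / diff(range(tex)) # 0..1 eosin density
    # background: white-ish through pink as eosin density rises
    base <- list(c(247, 244, 246), c(238, 160, 190))
    rgb <- array(0, c(h, w, 3))
    for (k in 1:3) rgb[, , k] <- base[[1]][k] + (base[[2]][k] - base[[1]][k]) * tex
    purple <- c(94, 44, 130)
    ys <- stats::runif(n_nuclei, 5, h - 5)
    xs <- stats::runif(n_nuclei, 5, w - 5)
    rr <- stats::runif(n_nuclei, 3, 7)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_nuclei)) {
      m <- ((yy - ys[i])^2 + (xx - xs[i])^2) <= rr[i]^2
      for (k in 1:3) {
        ch <- rgb[, , k]
        ch[m] <- purple[k]
        rgb[, , k] <- ch
      }
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))
    list(rgb = rgb, gray = rgb_to_gray(rgb))
  })
}

#' Benchmark phantom for pipeline sensitivity studies
#'
#' The stated world of the segmentation benchmark: a ~200^3 voxel block of
#' neuropil holding `n_cells` ellipsoidal cells with semi-axes uniform in
#' `radius_range` (the detection stage's target window), none touching the
#' border, at soma/neuropil contrast three times the noise level.  All
#' randomness derives from `seed`.
#'
#' @param seed integer seed.
#' @param shape volume dimensions.
#' @param n_cells number of cells.
#' @param radius_range semi-axis range in voxels.
#' @param spacing voxel size in nm.
#' @return A [phantom_spec()].
#' @export
benchmark_phantom_spec <- function(seed, shape = c(200, 200, 200),
                                   n_cells = 10, radius_range = c(15, 25),
                                   spacing = 200) {
  cells <- with_seed(seed + 90000L, lapply(seq_len(n_cells), function(i)
    cell_spec(center = NULL,
              radii = stats::runif(3, radius_range[1], radius_range[2]))))
  phantom_spec(shape = shape, spacing = spacing, cells = cells,
               rng_seed = seed)
}
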