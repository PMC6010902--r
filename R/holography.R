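#' Acquisition geometry of a cone-beam holotomography scan
#'
#' Bundles the instrument parameters of one scan row: photon energy, the
#' effective (post-binning) detector pixel, the focus-detector distance, and
#' the per-distance focus-sample distances D1.  The X-ray wavelength is
#' derived as lambda = hc / E.  The divergent beam gives each distance its
#' own geometric magnification M = (D1 + D2) / D1; the Fresnel scaling
#' theorem maps the cone beam to a parallel beam over the effective distance
#' D1 D2 / (D1 + D2) sampled at the demagnified pixel.
#'
#' @param photon_energy_kev photon energy in keV.
#' @param detector_pixel_um effective detector pixel in micrometres.
#' @param focus_detector_distance_mm focus-to-detector distance (D1 + D2).
#' @param d1_mm numeric vector of focus-to-sample distances in mm, one per
#'   propagation distance.
#' @param n_projections number of tomographic projections N.
#' @param exposure_s exposure time per projection, s.
#' @param photons_per_pixel_projection detected photons per pixel and
#'   projection.
#' @return An `AcquisitionGeometry` object (list with derived `wavelength_nm`,
#'   `magnification`, `effective_pixel_nm`, `distance_eff_mm`).
#' @export
acquisition_geometry <- function(photon_energy_kev = 17,
                                 detector_pixel_um = 3,
                                 focus_detector_distance_mm = 1208,
                                 d1_mm,
                                 n_projections = 1800,
                                 exposure_s = 0.25,
                                 photons_per_pixel_projection = 500) {
  if (photon_energy_kev <= 0) stop("geometry error: energy must be > 0",
                                   call. = FALSE)
  if (any(d1_mm <= 0) || any(d1_mm > focus_detector_distance_mm))
    stop("geometry error: need 0 < D1 <= focus-detector distance",
         call. = FALSE)
  mags <- vapply(d1_mm, function(d)
    magnification(d, focus_detector_distance_mm, detector_pixel_um)$M, 0)
  structure(list(
    photon_energy_kev = photon_energy_kev,
    wavelength_nm = 1239.84193 / (photon_energy_kev * 1000),
    detector_pixel_um = detector_pixel_um,
    focus_detector_distance_mm = focus_detector_distance_mm,
    d1_mm = d1_mm,
    n_projections = n_projections,
    exposure_s = exposure_s,
    photons_per_pixel_projection = photons_per_pixel_projection,
    magnification = mags,
    effective_pixel_nm = detector_pixel_um * 1000 / mags,
    distance_eff_mm = d1_mm * (focus_detector_distance_mm - d1_mm) /
      focus_detector_distance_mm), class = "AcquisitionGeometry")
}

#' Geometric magnification of the divergent beam
#'
#' `M = (D1 + D2) / D1` with `D1` the focus-sample and `D2` the
#' sample-detector distance.  Also returns the effective pixel
#' (detector pixel / M) and the Fresnel-scaled effective propagation
#' distance `D1 D2 / (D1 + D2)`.
#'
#' @param d1_mm focus-to-sample distance, mm.
#' @param focus_detector_distance_mm total focus-to-detector distance, mm.
#' @param detector_pixel_um detector pixel, micrometres.
#' @return list with `M`, `effective_pixel_nm`, `distance_eff_mm`.
#' @examples
#' # the 25 nm effective pixel of a scan at D1 = 10.066 mm
#' magnification(10.066, 1208, 3)$effective_pixel_nm
#' @export
magnification <- function(d1_mm, focus_detector_distance_mm,
                          detector_pixel_um = 3) {
  if (d1_mm <= 0 || d1_mm > focus_detector_distance_mm)
    stop("geometry error: need 0 < D1 <= focus-detector distance",
         call. = FALSE)
  M <- focus_detector_distance_mm / d1_mm
  d2 <- focus_detector_distance_mm - d1_mm
  list(M = M,
       effective_pixel_nm = detector_pixel_um * 1000 / M,
       distance_eff_mm = d1_mm * d2 / focus_detector_distance_mm)
}

#' Calibrate the focus-detector distance from one scan row
#'
#' The total distance follows from any (D1, effective pixel) pair as
#' `detector_pixel * D1 / l`; the instrument's value is recoverable from the
#' 200 nm prescan row (D1 = 80.533 mm, l = 200 nm, 3 um pixel) as 1208.0 mm.
#'
#' @param d1_mm focus-sample distance of the calibration row, mm.
#' @param effective_pixel_nm its effective pixel, nm.
#' @param detector_pixel_um detector pixel, micrometres.
#' @return focus-detector distance in mm.
#' @export
calibrate_focus_detector_distance <- function(d1_mm, effective_pixel_nm,
                                              detector_pixel_um = 3) {
  detector_pixel_um * 1000 * d1_mm / effective_pixel_nm
}

#' Photon budget of a tomographic scan
#'
#' Total detected photons per pixel over a scan: projections x photons per
#' pixel and projection x number of propagation distances.  Also reported in
#' units of 10^6 rounded to one decimal, the convention of instrument
#' parameter tables.
#'
#' @param n_projections number of projections N (>= 1).
#' @param photons_per_pixel_projection photons per pixel and projection.
#' @param n_distances number of propagation distances in the scan.
#' @return list with `photons` and `photons_1e6`.
#' @export
photons_per_pixel_scan <- function(n_projections,
                                   photons_per_pixel_projection,
                                   n_distances = 1) {
  if (n_projections < 1 || photons_per_pixel_projection < 1 || n_distances < 1)
    stop("parameter error: all inputs must be >= 1", call. = FALSE)
  ph <- n_projections * photons_per_pixel_projection * n_distances
  list(photons = ph, photons_1e6 = round(ph / 1e6, 1))
}

#' Canonical scan-parameter rows
#'
#' The instrument parameter table used throughout: effective pixel size l,
#' projections N, exposure t, photons per pixel and projection, and the
#' focus-sample distances D1 of each scan.  These printed values are inputs
#' to the geometry and photon-budget calculations.
#'
#' @return data.frame with one row per scan; `d1_mm` is a list column.
#' @export
table1_rows <- function() {
  rows <- list(
    list("cerebellum", 200, 1200, 0.25, 500, list(80.533)),
    list("cerebellum", 130, 1200, 0.25, 500,
         list(c(52.346, 54.592, 63.575, 82.226))),
    list("cerebellum", 50, 1200, 0.25, 500,
         list(c(20.133, 20.997, 24.452, 31.625))),
    list("cerebellum", 25, 1800, 0.25, 500,
         list(c(10.066, 10.499, 12.226, 15.812))),
    list("cortex", 200, 1200, 0.30, 600, list(80.533)),
    list("cortex", 100, 2000, 0.30, 600,
         list(c(40.266, 41.994, 48.904, 63.251))),
    list("cortex", 50, 2000, 0.30, 600,
         list(c(20.133, 20.997, 24.452, 31.625))),
    list("cerebellum_2", 200, 1200, 0.30, 600, list(80.533)),
    list("cerebellum_2", 100, 1900, 0.30, 600,
         list(c(40.266, 41.994, 48.904, 63.251))),
    list("cerebellum_2", 50, 1900, 0.30, 600,
         list(c(20.133, 20.997, 24.452, 31.625))))
  df <- data.frame(
    sample = vapply(rows, function(r) r[[1]], ""),
    l_nm = vapply(rows, function(r) r[[2]], 0),
    n_projections = vapply(rows, function(r) r[[3]], 0),
    exposure_s = vapply(rows, function(r) r[[4]], 0),
    photons_per_pixel_projection = vapply(rows, function(r) r[[5]], 0),
    stringsAsFactors = FALSE)
  df$d1_mm <- lapply(rows, function(r) r[[6]][[1]])
  df
}

fftfreq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Paraxial Fresnel propagation of a complex wave
#'
#' Propagates `amplitude * exp(i phase)` over `distance_eff_mm` with the
#' single-FFT transfer-function propagator `exp(-i pi lambda D f^2)` under
#' periodic boundary handling, and returns the intensity.  Total intensity is
#' conserved (Parseval).  A warning is raised when the propagator chirp or
#' the object phase exceed the grid's Nyquist criterion.
#'
#' @param phase_map 2-D matrix of phase in radians.
#' @param amplitude_map 2-D matrix of amplitude (default 1).
#' @param wavelength_nm X-ray wavelength, nm.
#' @param distance_eff_mm effective propagation distance, mm (>= 0).
#' @param pixel_nm grid sampling, nm.
#' @return matrix of intensities `|psi|^2`.
#' @export
fresnel_propagate <- function(phase_map, amplitude_map = NULL, wavelength_nm,
                              distance_eff_mm, pixel_nm) {
  if (is.null(amplitude_map))
    amplitude_map <- matrix(1, nrow(phase_map), ncol(phase_map))
  if (!all(dim(phase_map) == dim(amplitude_map)))
    stop("phase and amplitude maps must have the same shape", call. = FALSE)
  if (distance_eff_mm < 0) stop("distance must be >= 0", call. = FALSE)
  d_nm <- distance_eff_mm * 1e6
  n1 <- nrow(phase_map); n2 <- ncol(phase_map)
  if (d_nm > 0) {
    if (wavelength_nm * d_nm / pixel_nm^2 > min(n1, n2))
      warning("Fresnel propagator undersampled for this distance/pixel",
              call. = FALSE)
    gmax <- max(abs(diff(phase_map)), abs(t(diff(t(phase_map)))), 0)
    if (gmax > pi)
      warning("phase gradients exceed the propagator Nyquist criterion",
              call. = FALSE)
  }
  psi <- amplitude_map * exp(1i * phase_map)
  if (d_nm == 0) return(Mod(psi)^2)
  f1 <- fftfreq(n1, pixel_nm); f2 <- fftfreq(n2, pixel_nm)
  chi <- pi * wavelength_nm * d_nm *
    (outer(f1^2, rep(1, n2)) + outer(rep(1, n1), f2^2))
  Mod(ifft2(fft2(psi) * exp(-1i * chi)))^2
}

# bilinear sampling of matrix `m` at fractional 1-based coordinates
bilinear_sample <- function(m, ys, xs, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  y0 <- floor(ys); x0 <- floor(xs)
  ok <- y0 >= 1 & x0 >= 1 & y0 <= ny - 1 & x0 <= nx - 1
  # clamp one-past-edge samples onto the edge
  edge <- (ys >= 1 & xs >= 1 & ys <= ny & xs <= nx) & !ok
  y0c <- pmin(pmax(y0, 1), ny - 1); x0c <- pmin(pmax(x0, 1), nx - 1)
  fy <- ys - y0c; fx <- xs - x0c
  i00 <- cbind(y0c, x0c); i10 <- cbind(y0c + 1, x0c)
  i01 <- cbind(y0c, x0c + 1); i11 <- cbind(y0c + 1, x0c + 1)
  v <- (1 - fy) * (1 - fx) * m[i00] + fy * (1 - fx) * m[i10] +
       (1 - fy) * fx * m[i01] + fy * fx * m[i11]
  v[!(ok | edge)] <- fill
  v
}

# center-anchored rescale of `m` by `factor` (output pixel = input / factor)
rescale_image <- function(m, factor, out_dim = dim(m), fill = 0) {
  cy <- (nrow(m) + 1) / 2; cx <- (ncol(m) + 1) / 2
  oy <- (out_dim[1] + 1) / 2; ox <- (out_dim[2] + 1) / 2
  ys <- cy + (seq_len(out_dim[1]) - oy) / factor
  xs <- cx + (seq_len(out_dim[2]) - ox) / factor
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(m, g$y, g$x, fill = fill), out_dim[1], out_dim[2])
}

shift_image <- function(m, dy, dx, fill = 0) {
  g <- expand.grid(y = seq_len(nrow(m)) + dy, x = seq_len(ncol(m)) + dx)
  matrix(bilinear_sample(m, g$y, g$x, fill = fill), nrow(m), ncol(m))
}

#' Simulate a multi-distance hologram series
#'
#' For each focus-sample distance of the geometry, the object phase map is
#' resampled to that distance's effective pixel (the coarser magnifications
#' see a wider field), Fresnel-propagated over the Fresnel-scaled effective
#' distance, scaled to the photon budget and degraded with Poisson noise.
#' A noisy flat field accompanies every distance.  Deterministic under
#' `rng_seed`; `photons = Inf` disables noise.
#'
#' @param phase_map object-plane phase map sampled at the finest effective
#'   pixel of `geometry`.
#' @param geometry an [acquisition_geometry()].
#' @param rng_seed integer seed.
#' @param photons photons per pixel (default the geometry's); `Inf` for
#'   noiseless holograms.
#' @return A `HologramSet`: list with `images`, `flats` (lists of matrices),
#'   `magnification`, `pixel_nm`, `distance_eff_mm`, `photons`.
#' @export
simulate_hologram_series <- function(phase_map, geometry, rng_seed = 1L,
                                     photons = NULL) {
  stopifnot(inherits(geometry, "AcquisitionGeometry"))
  if (any(!is.finite(phase_map)))
    stop("geometry mismatch: projections must be finite", call. = FALSE)
  if (is.null(photons)) photons <- geometry$photons_per_pixel_projection
  px <- geometry$effective_pixel_nm
  base <- min(px)
  with_seed(rng_seed, {
    images <- list(); flats <- list()
    for (k in seq_along(geometry$d1_mm)) {
      ph_k <- rescale_image(phase_map, base / px[k], fill = 0)
      I <- fresnel_propagate(ph_k, NULL, geometry$wavelength_nm,
                             geometry$distance_eff_mm[k], px[k])
      if (is.finite(photons)) {
        img <- matrix(stats::rpois(length(I), photons * pmax(I, 0)),
                      nrow(I), ncol(I))
        flat <- matrix(stats::rpois(length(I), photons), nrow(I), ncol(I))
      } else {
        img <- I
        flat <- matrix(1, nrow(I), ncol(I))
      }
      images[[k]] <- img
      flats[[k]] <- flat
    }
    structure(list(images = images, flats = flats,
                   magnification = geometry$magnification,
                   pixel_nm = px,
                   distance_eff_mm = geometry$distance_eff_mm,
                   photons = photons), class = "HologramSet")
  })
}

#' Flat-field normalization and magnification alignment
#'
#' Divides each hologram by its flat field, rescales all distances to the
#' finest effective pixel (center-anchored bilinear zoom), and removes
#' residual translation against the first distance by cross-correlation
#' registration.
#'
#' @param h a `HologramSet`.
#' @return list with `stack` (list of aligned matrices), `pixel_nm`,
#'   `distance_eff_mm`, `offsets` (per-distance (dy, dx) removed).
#' @export
normalize_and_align <- function(h) {
  stopifnot(inherits(h, "HologramSet"))
  base <- min(h$pixel_nm)
  out <- list(); offs <- list()
  for (k in seq_along(h$images)) {
    flat <- h$flats[[k]]
    if (any(flat <= 0))
      stop("normalization error: flat field contains non-positive pixels",
           call. = FALSE)
    img <- h$images[[k]] / flat
    img <- rescale_image(img, h$pixel_nm[k] / base, fill = 1)
    if (k > 1) {
      reg <- translation_register_2d(out[[1]], img)
      img <- shift_image(img, reg$offset[1], reg$offset[2], fill = 1)
      offs[[k]] <- reg$offset
    } else offs[[k]] <- c(0, 0)
    out[[k]] <- img
  }
  list(stack = out, pixel_nm = base, distance_eff_mm = h$distance_eff_mm,
       offsets = offs)
}

#' Multi-distance CTF phase retrieval
#'
#' Least-squares inversion of the weak-object, pure-phase contrast transfer
#' function over all distances: with `chi_d = pi lambda D_d f^2`,
#' `phase_hat = sum_d sin(chi_d) I_hat_d / (2 sum_d sin^2(chi_d) + eps)`,
#' where `I_hat_d` is the Fourier transform of the flat-normalized contrast
#' `I_d - 1`.  The regularization `eps` (default `1e-3` of the peak
#' denominator) controls the zero-frequency and CTF-zero divisions.
#'
#' @param stack list of aligned flat-normalized hologram matrices.
#' @param wavelength_nm wavelength, nm.
#' @param distances_eff_mm effective distances, mm (one per stack entry).
#' @param pixel_nm grid sampling, nm.
#' @param regularization scalar `eps`; `NULL` for the default.
#' @return matrix of retrieved phase in radians.
#' @export
ctf_phase_retrieval <- function(stack, wavelength_nm, distances_eff_mm,
                                pixel_nm, regularization = NULL) {
  if (!length(stack)) stop("need at least one distance", call. = FALSE)
  if (length(stack) != length(distances_eff_mm))
    stop("one distance per hologram required", call. = FALSE)
  n1 <- nrow(stack[[1]]); n2 <- ncol(stack[[1]])
  f2g <- outer(fftfreq(n1, pixel_nm)^2, rep(1, n2)) +
         outer(rep(1, n1), fftfreq(n2, pixel_nm)^2)
  num <- matrix(0 + 0i, n1, n2)
  den <- matrix(0, n1, n2)
  for (k in seq_along(stack)) {
    chi <- pi * wavelength_nm * (distances_eff_mm[k] * 1e6) * f2g
    s <- sin(chi)
    num <- num + s * fft2(stack[[k]] - 1)
    den <- den + s^2
  }
  den <- 2 * den
  eps <- if (is.null(regularization)) 1e-3 * max(den) else regularization
  if (eps <= 0 && any(den == 0))
    stop("division guard: CTF denominator vanishes and regularization is 0",
         call. = FALSE)
  Re(ifft2(num / (den + eps)))
}

#' Forward Radon transform of a 2-D image
#'
#' Line integrals along equally spaced angles; used to build sinograms for
#' the reconstruction round-trip tests and the pipeline.
#'
#' @param image square matrix.
#' @param angles projection angles in radians.
#' @return matrix `n_detector x n_angles`.
#' @export
radon_project <- function(image, angles) {
  n <- nrow(image)
  stopifnot(ncol(image) == n)
  ctr <- (n + 1) / 2
  idx <- seq_len(n) - ctr
  sino <- matrix(0, n, length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a]
    # sample the image rotated by -th, then integrate along rows
    g <- expand.grid(t = idx, s = idx)
    ys <- ctr + g$t * cos(th) - g$s * sin(th)
    xs <- ctr + g$t * sin(th) + g$s * cos(th)
    vals <- matrix(bilinear_sample(image, ys, xs), n, n)
    sino[, a] <- rowSums(vals)
  }
  sino
}

fbp_slice <- function(sino, angles) {
  n <- nrow(sino)
  npad <- 2^ceiling(log2(2 * n))
  ramp <- abs(fftfreq(npad))
  filt <- matrix(0, n, ncol(sino))
  for (a in seq_len(ncol(sino))) {
    col <- c(sino[, a], rep(0, npad - n))
    filt[, a] <- Re(stats::fft(stats::fft(col) * ramp, inverse = TRUE) /
                      npad)[seq_len(n)]
  }
  ctr <- (n + 1) / 2
  g <- expand.grid(y = seq_len(n) - ctr, x = seq_len(n) - ctr)
  out <- numeric(n * n)
  for (a in seq_along(angles)) {
    th <- angles[a]
    t <- ctr + g$y * cos(th) + g$x * sin(th)
    t0 <- floor(t); ft <- t - t0
    ok <- t0 >= 1 & t0 <= n - 1
    v <- numeric(length(t))
    col <- filt[, a]
    v[ok] <- (1 - ft[ok]) * col[t0[ok]] + ft[ok] * col[t0[ok] + 1]
    out <- out + v
  }
  matrix(out * pi / (2 * length(angles)), n, n)
}

#' Filtered back projection reconstruction
#'
#' Ramp-filtered back projection of per-slice sinograms over equally spaced
#' angles covering 180 degrees.
#'
#' @param sinograms array `nz x n_detector x n_angles`, or a single
#'   `n_detector x n_angles` matrix for one slice.
#' @param angles projection angles in radians (>= 2).
#' @param spacing_nm voxel spacing of the reconstruction.
#' @return `Volume3D` of shape `nz x n x n`.
#' @export
fbp_reconstruct <- function(sinograms, angles, spacing_nm = 1) {
  if (length(angles) < 2) stop("need at least 2 angles", call. = FALSE)
  if (is.matrix(sinograms))
    sinograms <- array(sinograms, c(1, dim(sinograms)))
  nz <- dim(sinograms)[1]; n <- dim(sinograms)[2]
  out <- array(0, c(nz, n, n))
  for (z in seq_len(nz))
    out[z, , ] <- fbp_slice(matrix(sinograms[z, , ], n), angles)
  volume3d(out, spacing_nm)
}
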