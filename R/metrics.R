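#' Contrast-to-noise ratio from a two-Gaussian fit
#'
#' `CNR = |I1 - I2| / sqrt(sigma1^2 + sigma2^2)` between two homogeneous
#' components.  With ROI masks given, component moments come directly from
#' the ROIs; otherwise the intensity histogram is fitted with a two-Gaussian
#' mixture (weighted EM on 256 histogram bins, deterministic median-split
#' initialization).  CNR is invariant under affine intensity rescaling.
#'
#' @param v `Volume3D` or array.
#' @param roi_a,roi_b optional logical masks selecting the two components.
#' @param n_boot optional bootstrap-over-slices replicate count for a
#'   percentile interval on the histogram-mode CNR.
#' @param rng_seed seed for the bootstrap.
#' @return A `CnrFit` list: `I1`, `I2`, `sigma1`, `sigma2`, `cnr`,
#'   `residual`, `weights`, optional `interval`.
#' @export
cnr <- function(v, roi_a = NULL, roi_b = NULL, n_boot = 0, rng_seed = 1L) {
  arr <- if (is_volume3d(v)) v$voxels else v
  if (!is.null(roi_a) || !is.null(roi_b)) {
    if (is.null(roi_a) || is.null(roi_b))
      stop("both ROIs are required in ROI mode", call. = FALSE)
    if (!any(roi_a) || !any(roi_b)) stop("ROIs must be nonempty",
                                         call. = FALSE)
    fit <- list(I1 = mean(arr[roi_a]), I2 = mean(arr[roi_b]),
                sigma1 = stats::sd(arr[roi_a]), sigma2 = stats::sd(arr[roi_b]),
                residual = NA_real_, weights = c(mean(roi_a), mean(roi_b)))
  } else {
    fit <- fit_two_gaussians(as.vector(arr))
  }
  fit$cnr <- cnr_value(fit)
  if (n_boot > 0 && is.null(roi_a)) {
    d <- dim(arr)
    reps <- with_seed(rng_seed, vapply(seq_len(n_boot), function(i) {
      zs <- sample(d[1], replace = TRUE)
      f <- fit_two_gaussians(as.vector(arr[zs, , ]))
      cnr_value(f)
    }, 0))
    fit$interval <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  }
  structure(fit, class = "CnrFit")
}

cnr_value <- function(fit) {
  s <- sqrt(fit$sigma1^2 + fit$sigma2^2)
  if (s == 0) return(if (fit$I1 == fit$I2) 0 else Inf)
  abs(fit$I1 - fit$I2) / s
}

# weighted EM fit of a two-Gaussian mixture to a 256-bin histogram
fit_two_gaussians <- function(x, nbins = 256, max_iter = 300, tol = 1e-10) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("fit error: constant intensities cannot be fit with two Gaussians",
         call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- hist(x, breaks = br, plot = FALSE)
  ctr <- h$mids; w <- h$counts
  keep <- w > 0
  ctr <- ctr[keep]; w <- w[keep]
  med <- stats::median(x)
  lo <- x <= med; hi <- !lo
  mu <- c(mean(x[lo]), mean(x[hi]))
  sg <- pmax(c(stats::sd(x[lo]), stats::sd(x[hi])), diff(rng) / nbins)
  pw <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pw[1] * stats::dnorm(ctr, mu[1], sg[1])
    d2 <- pw[2] * stats::dnorm(ctr, mu[2], sg[2])
    tot <- d1 + d2 + 1e-300
    r1 <- d1 / tot
    ll <- sum(w * log(tot))
    n1 <- sum(w * r1); n2 <- sum(w * (1 - r1))
    pw <- c(n1, n2) / (n1 + n2)
    mu <- c(sum(w * r1 * ctr) / n1, sum(w * (1 - r1) * ctr) / n2)
    sg <- sqrt(pmax(c(sum(w * r1 * (ctr - mu[1])^2) / n1,
                      sum(w * (1 - r1) * (ctr - mu[2])^2) / n2),
                    (diff(rng) / nbins / 4)^2))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  if (min(pw) < 0.01)
    stop(sprintf(
      "fit error: degenerate two-Gaussian fit (component weights %.3f/%.3f)",
      pw[1], pw[2]), call. = FALSE)
  dens <- pw[1] * stats::dnorm(ctr, mu[1], sg[1]) +
          pw[2] * stats::dnorm(ctr, mu[2], sg[2])
  emp <- w / sum(w) / diff(br)[1]
  ord <- order(mu)
  list(I1 = mu[ord[1]], I2 = mu[ord[2]],
       sigma1 = sg[ord[1]], sigma2 = sg[ord[2]],
       residual = sqrt(mean((dens - emp)^2)), weights = pw[ord])
}

#' @export
print.CnrFit <- function(x, ...) {
  cat(sprintf("CnrFit: CNR = %.4g  (I1 = %.4g +- %.3g, I2 = %.4g +- %.3g)\n",
              x$cnr, x$I1, x$sigma1, x$I2, x$sigma2))
  if (!is.null(x$interval))
    cat(sprintf("  bootstrap 95%% interval [%.4g, %.4g]\n",
                x$interval[1], x$interval[2]))
  invisible(x)
}

#' Edge-based resolution from the normalized MTF
#'
#' Extracts the edge-spread profile across a step edge (optionally the
#' voxel-wise median over `median_slices` slices, the noise-robust variant
#' used for low-CNR data), differentiates it to the line-spread function,
#' takes the Fourier magnitude, normalizes to 1 at the lowest nonzero
#' frequency, and reports the *half-period* of the 10% crossing as the
#' upper-limit spatial resolution in nm.  When the nMTF never falls below
#' 10% inside the sampled band the Nyquist half-period (one voxel) is
#' reported with `at_band_edge = TRUE`.
#'
#' @param v `Volume3D` containing the edge (e.g. from
#'   [generate_edge_phantom()], whose `edge` metadata supplies the axis).
#' @param edge_region optional list of index ranges `list(z =, y =, x =)`
#'   (1-based) restricting the analysis region.
#' @param median_slices number of slices the profile is median-filtered
#'   over (1 = none).
#' @param edge_axis axis perpendicular to the edge plane (default from
#'   `v$edge`, else the last axis).
#' @return A `ResolutionEstimate` list: `resolution_nm`, `nmtf`
#'   (data.frame `freq_per_nm`, `value`), `f10_per_nm`, `median_slices`,
#'   `at_band_edge`.
#' @export
nmtf_resolution <- function(v, edge_region = NULL, median_slices = 1,
                            edge_axis = NULL) {
  stopifnot(is_volume3d(v))
  arr <- v$voxels
  if (!is.null(edge_region)) {
    d <- dim(arr)
    rg <- lapply(seq_len(3), function(i) {
      nm <- c("z", "y", "x")[i]
      if (!is.null(edge_region[[nm]])) edge_region[[nm]] else seq_len(d[i])
    })
    arr <- arr[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  }
  if (is.null(edge_axis))
    edge_axis <- if (!is.null(v$edge)) v$edge$axis else 3L
  perm <- switch(edge_axis, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
  a <- aperm(arr, perm) # -> [slice, row, position-across-edge]
  ns <- dim(a)[1]
  if (median_slices > ns)
    stop("median_slices exceeds the available slice count", call. = FALSE)
  if (median_slices > 1) {
    sub <- a[seq_len(median_slices), , , drop = FALSE]
    esf2d <- apply(sub, c(2, 3), stats::median)
  } else {
    esf2d <- matrix(a[1, , ], dim(a)[2], dim(a)[3])
    if (ns > 1) esf2d <- apply(a, c(2, 3), mean)
  }
  esf <- colMeans(esf2d)
  lsf <- diff(esf)
  n <- length(lsf)
  mtf <- Mod(stats::fft(lsf))
  freqs <- fftfreq(n, v$spacing)
  pos <- which(freqs > 0)
  f <- freqs[pos]
  m <- mtf[pos]
  nmtf <- m / m[1] # normalize at the lowest nonzero frequency
  below <- which(nmtf < 0.1)
  half_band <- f <= max(f) * (1 + 1e-9)
  if (!length(below)) {
    res <- v$spacing # Nyquist half-period: one voxel
    f10 <- 1 / (2 * v$spacing)
    at_edge <- TRUE
  } else {
    k <- below[1]
    if (k == 1) {
      f10 <- f[1]
    } else {
      # linear interpolation of the crossing
      fr <- (nmtf[k - 1] - 0.1) / (nmtf[k - 1] - nmtf[k])
      f10 <- f[k - 1] + fr * (f[k] - f[k - 1])
    }
    res <- 1 / (2 * f10)
    at_edge <- FALSE
  }
  structure(list(resolution_nm = res,
                 nmtf = data.frame(freq_per_nm = f, value = nmtf)[half_band, ],
                 f10_per_nm = f10, median_slices = median_slices,
                 at_band_edge = at_edge), class = "ResolutionEstimate")
}

#' @export
print.ResolutionEstimate <- function(x, ...) {
  cat(sprintf("ResolutionEstimate: %.1f nm (10%% nMTF crossing%s)\n",
              x$resolution_nm,
              if (x$at_band_edge) ", flagged at band edge" else ""))
  invisible(x)
}

#' Object-level detection sensitivity
#'
#' `S = TP / T`: the fraction of detected objects that correspond to true
#' cells.  A detected object counts as a true positive when its centroid
#' falls inside a ground-truth soma and its overlap with that cell covers at
#' least half of the smaller of the two objects.  Label permutations do not
#' affect the value.
#'
#' @param result `SegmentationResult` (or integer label `Volume3D`).
#' @param truth ground-truth label `Volume3D` (phantom encoding of
#'   [compartment_mask()] or plain per-cell integers).
#' @param min_overlap fraction of the smaller object that must overlap.
#' @param truth_encoding `"phantom"` when `truth` uses the per-cell
#'   compartment decades of [compartment_mask()], `"plain"` when it holds
#'   one integer per cell.
#' @return list with `S`, `TP`, `T`, `truth_cells`, `truth_found`, and the
#'   per-object match table.  With zero detected objects `S` is `NA`
#'   (undefined) and a message is emitted.
#' @export
sensitivity <- function(result, truth, min_overlap = 0.5,
                        truth_encoding = c("phantom", "plain")) {
  truth_encoding <- match.arg(truth_encoding)
  det <- if (inherits(result, "SegmentationResult")) result$labels else result
  stopifnot_congruent(det, truth)
  dlab <- det$voxels
  tl <- truth$voxels
  # collapse phantom compartment encoding to one id per cell
  tcell <- array(0L, dim(tl))
  nz <- tl > 0L
  tcell[nz] <- if (truth_encoding == "phantom")
    (tl[nz] - 1L) %/% 10L + 1L else tl[nz]
  dT <- max(dlab)
  truth_ids <- sort(unique(tcell[tcell > 0L]))
  if (dT == 0L) {
    message("no detected objects: sensitivity undefined")
    return(list(S = NA_real_, TP = 0L, T = 0L,
                truth_cells = length(truth_ids), truth_found = 0L,
                matches = data.frame()))
  }
  tsize <- tabulate(tcell[tcell > 0L], nbins = max(tcell))
  dsize <- tabulate(dlab[dlab > 0L], nbins = dT)
  matches <- data.frame(id = seq_len(dT), matched_cell = NA_integer_,
                        overlap = 0, tp = FALSE)
  found <- logical(length(truth_ids))
  d <- dim(dlab)
  idx <- which(dlab > 0L)
  ids <- dlab[idx]
  cz <- (idx - 1L) %% d[1]; cy <- ((idx - 1L) %/% d[1]) %% d[2]
  cx <- (idx - 1L) %/% (d[1] * d[2])
  cen_z <- rowsum(cz, ids) / dsize
  cen_y <- rowsum(cy, ids) / dsize
  cen_x <- rowsum(cx, ids) / dsize
  for (k in seq_len(dT)) {
    sel <- idx[ids == k]
    ov <- tcell[sel]
    ov <- ov[ov > 0L]
    if (!length(ov)) next
    tab <- tabulate(ov)
    cell <- which.max(tab)
    overlap <- tab[cell]
    ci <- round(c(cen_z[k], cen_y[k], cen_x[k])) + 1L
    ci <- pmin(pmax(ci, 1L), d)
    centroid_in <- tcell[ci[1], ci[2], ci[3]] == cell
    ok <- centroid_in &&
      overlap >= min_overlap * min(dsize[k], tsize[cell])
    matches$matched_cell[k] <- cell
    matches$overlap[k] <- overlap
    matches$tp[k] <- ok
    if (ok) found[match(cell, truth_ids)] <- TRUE
  }
  TP <- sum(matches$tp)
  list(S = TP / dT, TP = TP, T = dT,
       truth_cells = length(truth_ids), truth_found = sum(found),
       matches = matches)
}

#' Ellipse curvature of a segmented object
#'
#' Assuming elliptical cells, the envelope curvature is `R = a^2 / b` with
#' `2a` the major and `2b` the minor axis.  Axes can be given directly or
#' fitted to a 2-D mask (inertia tensor of the voxel coordinates: for a
#' solid ellipse the semi-axes are twice the principal standard deviations);
#' a 3-D mask is reduced to its mid-slice through the centroid.
#'
#' @param x either `c(a, b)` semi-axes in physical units, or a logical 2-D /
#'   3-D mask.
#' @param spacing physical size of one voxel (any length unit; the result is
#'   in the same unit).  Ignored when axes are given directly.
#' @return list with `R`, `a`, `b`, `equivalent_diameter` (same unit).
#' @export
ellipse_curvature <- function(x, spacing = 1) {
  if (is.numeric(x) && is.null(dim(x))) {
    a <- max(x[1], x[2]); b <- min(x[1], x[2])
    if (b <= 0) stop("degenerate ellipse: b must be > 0", call. = FALSE)
    return(list(R = a^2 / b, a = a, b = b,
                equivalent_diameter = 2 * sqrt(a * b)))
  }
  m <- x != 0
  if (length(dim(m)) == 3L) {
    zc <- round(mean(which(apply(m, 1, any))))
    m <- m[zc, , ]
  }
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) < 4) stop("degenerate ellipse: too few voxels", call. = FALSE)
  n <- nrow(pts)
  cv <- stats::cov(pts) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  a <- 2 * sqrt(ev[1]) * spacing
  b <- 2 * sqrt(ev[2]) * spacing
  if (b <= 0) stop("degenerate ellipse: b must be > 0", call. = FALSE)
  list(R = a^2 / b, a = a, b = b, equivalent_diameter = 2 * sqrt(a * b))
}

#' Translation registration by cross-correlation
#'
#' Finds the integer shift maximizing the circular normalized
#' cross-correlation between two equally shaped arrays, refined per axis by
#' a quadratic fit through the correlation peak.  Applying the offset to
#' `moving` (sampling it at `index + offset`) aligns it with `fixed`.
#'
#' @param fixed,moving `Volume3D`, arrays or matrices of identical shape.
#' @param min_peak normalized correlation below which the result is flagged
#'   low-confidence.
#' @return list with `offset` (per axis, voxels), `peak` (normalized
#'   correlation), `low_confidence`.
#' @export
translation_register <- function(fixed, moving, min_peak = 0.3) {
  a <- if (is_volume3d(fixed)) fixed$voxels else fixed
  b <- if (is_volume3d(moving)) moving$voxels else moving
  if (!identical(dim(a), dim(b)))
    stop("fixed and moving must have the same shape", call. = FALSE)
  d <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0),
                      inverse = TRUE)) / length(a0)
  denom <- sqrt(sum(a0^2) * sum(b0^2)) / length(a0)
  ncc <- cc / max(denom, .Machine$double.eps)
  pk <- which.max(ncc)
  sub <- arrayInd(pk, d) - 1L
  offset <- ifelse(sub > d / 2, sub - d, sub)
  frac <- numeric(length(d))
  for (ax in seq_along(d)) {
    if (d[ax] < 3) next
    at <- function(delta) {
      i <- sub
      i[ax] <- (sub[ax] + delta) %% d[ax]
      ncc[matrix(i + 1L, 1)]
    }
    cm <- at(-1); c0 <- at(0); cp <- at(1)
    den <- cm - 2 * c0 + cp
    if (den < 0) frac[ax] <- 0.5 * (cm - cp) / den
  }
  peak <- max(ncc)
  list(offset = as.numeric(offset) + frac, peak = peak,
       low_confidence = peak < min_peak)
}

# 2-D convenience wrapper used by hologram alignment
translation_register_2d <- function(fixed, moving) {
  r <- translation_register(array(fixed, c(dim(fixed), 1)),
                            array(moving, c(dim(moving), 1)))
  list(offset = r$offset[1:2], peak = r$peak,
       low_confidence = r$low_confidence)
}

#' Running median over slices
#'
#' Per-pixel median over a running window of `n` slices along the
#' tomographic (first) axis; the smoothing used for noisy renderings.
#' The window shrinks symmetrically at the volume ends.
#'
#' @param v `Volume3D`.
#' @param n window length (odd preferred; must not exceed the slice count).
#' @return filtered `Volume3D`.
#' @export
median_over_slices <- function(v, n) {
  stopifnot(is_volume3d(v))
  d <- dim(v$voxels)
  if (n > d[1]) stop("window exceeds the slice count", call. = FALSE)
  out <- cpp_median_axis0(as.numeric(v$voxels), as.integer(d), as.integer(n))
  volume3d(array(out, d), v$spacing, v$origin)
}

#' Histology-driven colour transfer
#'
#' Builds a gray-to-RGB lookup from a pixel-aligned histology pair: pixels
#' of the RGB section are binned on their gray transform (integer bins
#' 0..255), each bin's RGB is averaged, gaps inside the occupied range are
#' linearly interpolated, and values beyond it clamp to the nearest occupied
#' bin (with a warning).  The lookup applied to a tomogram slice renders it
#' in the palette of the stained section.
#'
#' @param gray numeric matrix of gray values on the 0..255 scale (see
#'   [gray_rescale()]).
#' @param histology_rgb `h x w x 3` RGB image, 0..255.
#' @param histology_gray its grayscale transform (same shape, 0..255),
#'   e.g. from [rgb_to_gray()].
#' @return `h x w x 3` RGB array.
#' @export
hne_color_transfer <- function(gray, histology_rgb, histology_gray) {
  if (!all(dim(histology_rgb)[1:2] == dim(histology_gray)))
    stop("histology pair must be pixel-aligned", call. = FALSE)
  hg <- pmin(pmax(round(as.vector(histology_gray)), 0), 255)
  lut <- matrix(NA_real_, 256, 3)
  for (k in 1:3) {
    ch <- as.vector(histology_rgb[, , k])
    mns <- rowsum(ch, hg) / as.vector(table(hg))
    lut[as.integer(rownames(rowsum(ch, hg))) + 1L, k] <- mns
  }
  occupied <- which(!is.na(lut[, 1]))
  for (k in 1:3)
    lut[, k] <- stats::approx(occupied, lut[occupied, k], xout = 1:256,
                              rule = 2)$y
  g <- round(as.vector(gray))
  if (any(g < min(occupied) - 1L) || any(g > max(occupied) - 1L))
    warning("gray values beyond the histology range were clamped",
            call. = FALSE)
  g <- pmin(pmax(g, 0), 255)
  out <- array(0, c(dim(gray), 3))
  for (k in 1:3) out[, , k] <- matrix(lut[g + 1L, k], nrow(gray), ncol(gray))
  out
}

#' Rescale intensities to the 0..255 gray convention
#'
#' @param x numeric array.
#' @param from range mapped to 0..255 (default the data range).
#' @return array of the same shape on the 0..255 scale.
#' @export
gray_rescale <- function(x, from = range(x)) {
  if (diff(from) == 0) return(array(127.5, dim(x)))
  pmin(pmax((x - from[1]) / diff(from) * 255, 0), 255)
}

#' Serialize a metrics report
#'
#' Writes any list of metric results (CNR fits, resolution estimates,
#' sensitivity, curvatures, offsets) as JSON with full numeric precision;
#' [read_metrics_report()] restores it losslessly.
#'
#' @param report named list.
#' @param path output file.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "columns")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
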