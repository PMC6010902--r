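#' Parameters of the sparse-field level-set refinement
#'
#' Second stage of the automated segmentation.  Defaults are the published
#' schedule: slice-wise 2-D evolution with 900 iterations at smoothness
#' weight 0.01, a 3-D step with 60 iterations at weight 1, and removal of
#' objects below 300 voxels afterwards.
#'
#' @param n_iterations_2d,zeta_2d slice-wise stage iteration count and
#'   curve-smoothness weight.
#' @param n_iterations_3d,zeta_3d volumetric stage settings.
#' @param min_final_voxels final minimum object size.
#' @return An `SfmParams` object.
#' @export
sfm_params <- function(n_iterations_2d = 900, zeta_2d = 0.01,
                       n_iterations_3d = 60, zeta_3d = 1,
                       min_final_voxels = 300) {
  if (n_iterations_2d < 0 || n_iterations_3d < 0)
    stop("parameter error: iteration counts must be >= 0", call. = FALSE)
  if (zeta_2d < 0 || zeta_3d < 0)
    stop("parameter error: zeta must be >= 0", call. = FALSE)
  structure(list(n_iterations_2d = as.integer(n_iterations_2d),
                 zeta_2d = zeta_2d,
                 n_iterations_3d = as.integer(n_iterations_3d),
                 zeta_3d = zeta_3d,
                 min_final_voxels = as.integer(min_final_voxels)),
            class = "SfmParams")
}

#' Sparse-field level-set evolution
#'
#' Evolves a signed level-set function from `init_mask` under a two-phase
#' region data force (separation of inside/outside mean intensities) plus
#' `zeta`-weighted mean-curvature smoothing, updating only the five-layer
#' narrow band around the zero level set.  Works on 2-D matrices and 3-D
#' arrays.  `n_iterations = 0` returns the initialization unchanged.
#'
#' @param image matrix, 3-D array or `Volume3D`.
#' @param init_mask logical/integer mask of the same shape; must be nonempty
#'   for nonzero iteration counts.
#' @param n_iterations number of evolution steps.
#' @param zeta relative weight of curve smoothness against the (normalized)
#'   data force.
#' @param details return the level-set function and band diagnostics too?
#' @param region_means optional fixed `c(inside, outside)` mean intensities;
#'   by default both are re-estimated from the evolving partition every
#'   iteration (Chan-Vese).  Fixed means make the contour shrink away on
#'   content-free slices, which the semi-automated propagation relies on.
#' @return the evolved interior mask (integer array shaped like `image`), or
#'   a list with `mask`, `phi`, `iterations`, `vanished`, `band_size` when
#'   `details = TRUE`.  If the contour vanishes a warning is raised and the
#'   empty mask returned.
#' @export
sfm_evolve <- function(image, init_mask, n_iterations, zeta,
                       details = FALSE, region_means = NULL) {
  arr <- if (is_volume3d(image)) image$voxels else image
  m <- if (is_volume3d(init_mask)) init_mask$voxels else init_mask
  d <- dim(arr)
  if (is.null(d)) stop("image must be a matrix or 3-D array", call. = FALSE)
  if (!identical(dim(m), d))
    stop("init mask shape does not match image", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  msk <- as.integer(m != 0)
  if (n_iterations > 0 && !any(msk != 0L))
    stop("initialization mask is empty", call. = FALSE)
  if (is.null(region_means)) region_means <- c(NA_real_, NA_real_)
  res <- cpp_sfm(as.numeric(arr), as.integer(d), msk,
                 as.integer(n_iterations), zeta,
                 region_means[1], region_means[2])
  if (isTRUE(res$vanished))
    warning("level-set contour vanished; returning empty mask",
            call. = FALSE)
  mask <- array(res$mask, dim(arr))
  if (!details) return(mask)
  list(mask = mask, phi = array(res$phi, dim(arr)),
       iterations = res$iterations, vanished = res$vanished,
       band_size = res$band_size)
}

#' Per-object statistics of a label volume
#'
#' @param labels integer array or `Volume3D` of object labels (0 =
#'   background).
#' @param spacing_nm voxel size used for physical measurements.
#' @return data.frame with voxel count, 0-based centroid, border flag,
#'   inertia-ellipsoid semi-axes (voxels, `a >= b >= c`) and equivalent
#'   diameter.
#' @export
object_stats <- function(labels, spacing_nm = NULL) {
  lab <- if (is_volume3d(labels)) labels$voxels else labels
  if (is.null(spacing_nm))
    spacing_nm <- if (is_volume3d(labels)) labels$spacing else 1
  d <- dim(lab)
  idx <- which(lab > 0L)
  if (!length(idx))
    return(cbind(empty_object_table()[, 1:6],
                 data.frame(a = numeric(0), b = numeric(0), c = numeric(0),
                            equivalent_diameter = numeric(0))))
  ids <- lab[idx]
  ulab <- sort(unique(ids))
  cz <- (idx - 1L) %% d[1]
  cy <- ((idx - 1L) %/% d[1]) %% d[2]
  cx <- (idx - 1L) %/% (d[1] * d[2])
  border_ids <- setdiff(labels_touching_border(lab), 0L)
  groups <- split(seq_along(ids), ids)
  rows <- lapply(ulab, function(u) {
    g <- groups[[as.character(u)]]
    pts <- cbind(cz[g], cy[g], cx[g])
    n <- nrow(pts)
    ctr <- colMeans(pts)
    ax <- c(NA_real_, NA_real_, NA_real_)
    if (n >= 4) {
      ev <- sort(eigen(stats::cov(pts) * (n - 1) / n,
                       symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ax <- sqrt(5 * pmax(ev, 0)) # solid-ellipsoid variance a^2/5
    }
    data.frame(id = u, voxels = n,
               centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
               border_flag = u %in% border_ids,
               a = ax[1], b = ax[2], c = ax[3],
               equivalent_diameter = 2 * (3 * n / (4 * pi))^(1 / 3))
  })
  out <- do.call(rbind, rows)
  out$equivalent_diameter_nm <- out$equivalent_diameter * spacing_nm
  rownames(out) <- NULL
  out
}

finalize_segmentation <- function(mask_arr, v, min_final_voxels) {
  d <- dim(mask_arr)
  lab <- array(cpp_label_components(mask_arr != 0, as.integer(d), 26L), d)
  ncomp <- max(lab)
  if (ncomp > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which(sizes >= min_final_voxels)
    newid <- integer(ncomp)
    newid[keep] <- seq_along(keep)
    idx <- which(lab > 0L)
    out <- array(0L, d)
    out[idx] <- newid[lab[idx]]
    lab <- out
  }
  labels <- volume3d(lab, v$spacing, v$origin)
  structure(list(labels = labels, objects = object_stats(labels)),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: %d object(s)\n", nrow(x$objects)))
  if (nrow(x$objects)) print(utils::head(x$objects, 20))
  invisible(x)
}

#' Fully automated two-step segmentation
#'
#' Runs the published two-step framework: the multi-scale Hessian detection
#' ([frangi_response()] + [make_initialization_mask()]) provides the
#' initialization, which is refined slice-by-slice by 2-D sparse-field
#' evolution, stacked, refined by a 3-D sparse-field step, and finally
#' cleaned of objects below `sp$min_final_voxels`.  Deterministic: identical
#' input and parameters give identical labels.
#'
#' @param v intensity `Volume3D`.
#' @param fp a [frangi_params()].
#' @param sp an [sfm_params()].
#' @return A `SegmentationResult` (integer label `Volume3D` plus object
#'   statistics).
#' @export
segment_automated <- function(v, fp, sp) {
  stopifnot(inherits(sp, "SfmParams"))
  vv <- as_volume3d(v)
  resp <- frangi_response(vv, fp)
  init <- suppressWarnings(make_initialization_mask(resp, fp))
  seg2d <- sfm_slicewise(vv$voxels, init$mask$voxels != 0L,
                         sp$n_iterations_2d, sp$zeta_2d)
  if (!any(seg2d))
    return(finalize_segmentation(array(0L, dim(vv$voxels)), vv,
                                 sp$min_final_voxels))
  mask3d <- suppressWarnings(
    sfm_evolve(vv$voxels, seg2d, sp$n_iterations_3d, sp$zeta_3d))
  finalize_segmentation(mask3d, vv, sp$min_final_voxels)
}

# slice-wise 2-D evolution along the first (tomographic) axis
sfm_slicewise <- function(arr, mask, n_iter, zeta) {
  d <- dim(arr)
  out <- array(0L, d)
  if (n_iter == 0) return(mask * 1L)
  for (z in seq_len(d[1])) {
    m <- mask[z, , ]
    if (!any(m)) next
    out[z, , ] <- suppressWarnings(
      sfm_evolve(matrix(arr[z, , ], d[2], d[3]),
                 matrix(m, d[2], d[3]), n_iter, zeta))
  }
  out
}

#' Semi-automated segmentation from seeds on one slice
#'
#' Emulates the expert-verification route: cells are annotated on one slice
#' and the annotation is propagated outward slice by slice, each converged
#' 2-D contour initializing the next slice, until the evolved mask vanishes;
#' the stacked result then goes through the same 3-D sparse-field step and
#' size cleanup as the automated route.
#'
#' @param v intensity `Volume3D`.
#' @param seed_slice_index 0-based index of the annotated slice.
#' @param seed_masks_on_slice logical/integer matrix (ny x nx) of seed
#'   regions on that slice.
#' @param sp an [sfm_params()].
#' @return A `SegmentationResult`.
#' @export
segment_semiautomated <- function(v, seed_slice_index, seed_masks_on_slice,
                                  sp) {
  stopifnot(inherits(sp, "SfmParams"))
  vv <- as_volume3d(v)
  d <- dim(vv$voxels)
  z0 <- seed_slice_index + 1L
  if (z0 < 1L || z0 > d[1])
    stop("seed slice outside volume", call. = FALSE)
  seed <- seed_masks_on_slice != 0
  if (!any(seed)) stop("seed masks are empty", call. = FALSE)
  if (!identical(dim(seed), d[2:3]))
    stop("seed mask shape does not match the slice", call. = FALSE)
  out <- array(0L, d)
  evolve_slice <- function(z, init, means = NULL) {
    if (!any(init)) return(matrix(0L, d[2], d[3]))
    suppressWarnings(sfm_evolve(matrix(vv$voxels[z, , ], d[2], d[3]),
                                init, sp$n_iterations_2d, sp$zeta_2d,
                                region_means = means))
  }
  cur <- evolve_slice(z0, seed)
  out[z0, , ] <- cur
  # freeze the intensity model of the annotated slice for the propagation,
  # so the contour dies out once it runs past the cell
  sl0 <- vv$voxels[z0, , ]
  means <- if (any(cur != 0) && any(cur == 0))
    c(mean(sl0[cur != 0]), mean(sl0[cur == 0])) else NULL
  up <- cur
  if (z0 < d[1]) for (z in (z0 + 1L):d[1]) {
    up <- evolve_slice(z, up != 0, means)
    if (!any(up != 0)) break
    out[z, , ] <- up
  }
  down <- cur
  if (z0 > 1L) for (z in (z0 - 1L):1L) {
    down <- evolve_slice(z, down != 0, means)
    if (!any(down != 0)) break
    out[z, , ] <- down
  }
  if (!any(out != 0))
    return(finalize_segmentation(array(0L, d), vv, sp$min_final_voxels))
  mask3d <- suppressWarnings(
    sfm_evolve(vv$voxels, out, sp$n_iterations_3d, sp$zeta_3d))
  finalize_segmentation(mask3d, vv, sp$min_final_voxels)
}

#' Seeded region growing
#'
#' Intensity-based flood fill used for subcellular structures of distinctly
#' higher electron density (soma, nuclear envelope, nucleolus): from each
#' seed, 6-connected voxels join while their intensity stays within
#' `tolerance` of the running region mean.
#'
#' @param v intensity `Volume3D`.
#' @param seeds integer matrix of 0-based `(z, y, x)` rows, one region per
#'   seed.
#' @param tolerance gray-unit tolerance (>= 0).
#' @return A `SegmentationResult` with one label per seed.
#' @export
region_growing <- function(v, seeds, tolerance) {
  vv <- as_volume3d(v)
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  d <- dim(vv$voxels)
  lab <- cpp_region_grow(as.numeric(vv$voxels), as.integer(d), seeds,
                         tolerance, 6L)
  labels <- volume3d(array(lab, d), vv$spacing, vv$origin)
  structure(list(labels = labels, objects = object_stats(labels)),
            class = "SegmentationResult")
}
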