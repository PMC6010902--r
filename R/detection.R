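#' Parameters of the multi-scale Hessian detection stage
#'
#' The first stage of the automated segmentation: a multi-scale Hessian
#' objectness filter tuned to bright somata, binarized and size/border
#' filtered to give the level-set initialization mask.  Defaults are the
#' published operating point: `alpha = 0.5`, `beta = 0.1`, `gamma = 60`,
#' radius range 15-25 voxels with step 2, binarization threshold 0.01,
#' objects below 20 000 voxels or touching the volume margin rejected.
#'
#' `gamma` is a structureness cutoff in gray units and is only meaningful
#' relative to the data's gray range; the published value refers to 8-bit
#' range data, so with `gamma_scale = "range"` (default) the effective
#' cutoff is `gamma * robust_range / 255` where `robust_range` is the
#' 0.1-99.9 percentile intensity spread of the volume.  Use
#' `gamma_scale = "none"` to apply `gamma` verbatim.
#'
#' `blobness` selects the orientation of the second eigenvalue-ratio term:
#' `"enhance"` (default) treats deviation-from-blob as signal, the
#' objectness convention for 0-dimensional (soma-like) structures, which is
#' what makes the filter respond to high-intensity changes on cell margins
#' while `gamma` suppresses background noise; `"suppress"` is the textbook
#' vesselness orientation that keeps only tubular structures.
#'
#' @param alpha plate/line discrimination weight (> 0).
#' @param beta blob discrimination weight (> 0).
#' @param gamma structureness cutoff in gray units (> 0).
#' @param radius_min,radius_max,radius_step target radius range in voxels.
#' @param binarize_threshold response threshold in (0, 1].
#' @param min_object_voxels minimum component size kept (>= 0).
#' @param exclude_border drop components touching any volume face?
#' @param sigma_per_radius scale mapping sigma = `sigma_per_radius * r`.
#' @param blobness `"enhance"` or `"suppress"` (see above).
#' @param polarity `"bright"` for bright-on-dark structures, `"dark"` for
#'   inverted data.
#' @param gamma_scale `"range"` or `"none"` (see above).
#' @return A `FrangiParams` object.
#' @export
frangi_params <- function(alpha = 0.5, beta = 0.1, gamma = 60,
                          radius_min = 15, radius_max = 25, radius_step = 2,
                          binarize_threshold = 0.01,
                          min_object_voxels = 20000,
                          exclude_border = TRUE,
                          sigma_per_radius = 0.5,
                          blobness = c("enhance", "suppress"),
                          polarity = c("bright", "dark"),
                          gamma_scale = c("range", "none")) {
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("parameter error: alpha, beta, gamma must be > 0", call. = FALSE)
  if (radius_min > radius_max || radius_min <= 0)
    stop("parameter error: need 0 < radius_min <= radius_max", call. = FALSE)
  if (binarize_threshold <= 0 || binarize_threshold > 1)
    stop("parameter error: threshold must be in (0, 1]", call. = FALSE)
  if (min_object_voxels < 0)
    stop("parameter error: min_object_voxels must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 radius_min = radius_min, radius_max = radius_max,
                 radius_step = radius_step,
                 binarize_threshold = binarize_threshold,
                 min_object_voxels = min_object_voxels,
                 exclude_border = exclude_border,
                 sigma_per_radius = sigma_per_radius,
                 blobness = match.arg(blobness),
                 polarity = match.arg(polarity),
                 gamma_scale = match.arg(gamma_scale)),
            class = "FrangiParams")
}

effective_gamma <- function(p, arr) {
  if (p$gamma_scale == "none") return(p$gamma)
  q <- stats::quantile(arr, c(0.001, 0.999), names = FALSE)
  # floor keeps near-constant volumes from gating on float residue
  floor_g <- 1e-8 * max(abs(arr), 1)
  max(p$gamma * (q[2] - q[1]) / 255, floor_g)
}

# the 6 scale-normalized (x sigma^2) second Gaussian derivatives
hessian_components <- function(arr, sigma, truncate = 3) {
  d <- dim(arr)
  support <- 2L * as.integer(round(truncate * sigma)) + 1L
  if (min(d) < support)
    stop("volume smaller than the Hessian kernel support (", support,
         " voxels at sigma ", sigma, ")", call. = FALSE)
  s2 <- sigma^2
  ords <- list(zz = c(2, 0, 0), yy = c(0, 2, 0), xx = c(0, 0, 2),
               zy = c(1, 1, 0), zx = c(1, 0, 1), yx = c(0, 1, 1))
  lapply(ords, function(o)
    s2 * cpp_gaussian_deriv(as.numeric(arr), as.integer(d), sigma,
                            as.integer(o), truncate))
}

#' Eigenvalues of the scale-normalized 3-D Hessian
#'
#' Gaussian-derivative Hessian at scale `scale_sigma`, multiplied by
#' `sigma^2` (scale normalization), with eigenvalues sorted voxel-wise by
#' `|l1| <= |l2| <= |l3|`.
#'
#' @param v `Volume3D` or 3-D array.
#' @param scale_sigma Gaussian scale in voxels (> 0).
#' @return list of three `Volume3D` objects `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(v, scale_sigma) {
  if (scale_sigma <= 0) stop("parameter error: scale_sigma must be > 0",
                             call. = FALSE)
  vv <- as_volume3d(v)
  h <- hessian_components(vv$voxels, scale_sigma)
  ev <- cpp_eig3_volumes(h$zz, h$yy, h$xx, h$zy, h$zx, h$yx)
  d <- dim(vv$voxels)
  lapply(ev, function(e) volume3d(array(e, d), vv$spacing, vv$origin))
}

#' Multi-scale objectness (Frangi-type) response
#'
#' For each radius `r` in the configured range the Hessian is evaluated at
#' `sigma = sigma_per_radius * r` and combined into
#' `V = (1 - exp(-R_A^2 / 2 alpha^2)) * B(R_B) * (1 - exp(-S^2 / 2 gamma^2))`
#' with `R_A = |l2|/|l3|`, `R_B = |l1|/sqrt(|l2 l3|)`,
#' `S = sqrt(l1^2 + l2^2 + l3^2)`, and `B` either the blob-enhancing
#' `1 - exp(-R_B^2/2 beta^2)` or the tube-selecting `exp(-R_B^2/2 beta^2)`
#' (see [frangi_params()]).  The response is zero wherever the polarity
#' condition fails (`l2, l3 < 0` for bright structures) and the maximum over
#' scales is returned; values lie in [0, 1].
#'
#' @param v `Volume3D` or 3-D array.
#' @param p a [frangi_params()].
#' @return `Volume3D` response in [0, 1].
#' @export
frangi_response <- function(v, p) {
  stopifnot(inherits(p, "FrangiParams"))
  vv <- as_volume3d(v)
  arr <- vv$voxels
  gam <- effective_gamma(p, arr)
  radii <- seq(p$radius_min, p$radius_max, by = p$radius_step)
  best <- NULL
  for (r in radii) {
    h <- hessian_components(arr, p$sigma_per_radius * r)
    resp <- cpp_objectness(h$zz, h$yy, h$xx, h$zy, h$zx, h$yx,
                           p$alpha, p$beta, gam,
                           p$blobness == "enhance", p$polarity == "bright")
    best <- if (is.null(best)) resp else pmax(best, resp)
  }
  volume3d(array(best, dim(arr)), vv$spacing, vv$origin)
}

labels_touching_border <- function(lab) {
  d <- dim(lab)
  unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
           lab[, , 1], lab[, , d[3]]))
}

#' Initialization mask from the objectness response
#'
#' Binarizes the response at `p$binarize_threshold`, labels 26-connected
#' components, and drops components smaller than `p$min_object_voxels` or
#' (when `p$exclude_border`) touching any of the six volume faces.
#'
#' @param response `Volume3D` response in [0, 1].
#' @param p a [frangi_params()].
#' @return list with `mask` (integer `Volume3D`, surviving components
#'   relabelled 1..K) and `objects` (data.frame of all components with
#'   `id`, `voxels`, centroid, `border_flag`, `kept`).
#' @export
make_initialization_mask <- function(response, p) {
  stopifnot(inherits(p, "FrangiParams"))
  rv <- as_volume3d(response)
  arr <- rv$voxels
  if (min(arr) < 0 || max(arr) > 1)
    stop("response must lie in [0, 1]", call. = FALSE)
  d <- dim(arr)
  lab <- array(cpp_label_components(arr >= p$binarize_threshold,
                                    as.integer(d), 26L), d)
  ncomp <- max(lab)
  if (ncomp == 0L) {
    warning("empty initialization mask", call. = FALSE)
    return(list(mask = volume3d(array(0L, d), rv$spacing, rv$origin),
                objects = empty_object_table()))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  border_ids <- setdiff(labels_touching_border(lab), 0L)
  border <- seq_len(ncomp) %in% border_ids
  kept <- sizes >= p$min_object_voxels & !(p$exclude_border & border)
  idx <- which(lab > 0L)
  cz <- (idx - 1L) %% d[1]
  cy <- ((idx - 1L) %/% d[1]) %% d[2]
  cx <- (idx - 1L) %/% (d[1] * d[2])
  ids <- lab[idx]
  objects <- data.frame(
    id = seq_len(ncomp), voxels = sizes,
    centroid_z = as.vector(rowsum(cz, ids) / sizes),
    centroid_y = as.vector(rowsum(cy, ids) / sizes),
    centroid_x = as.vector(rowsum(cx, ids) / sizes),
    border_flag = border, kept = kept)
  newid <- integer(ncomp)
  newid[kept] <- seq_len(sum(kept))
  out <- array(0L, d)
  out[idx] <- newid[ids]
  if (!any(kept)) warning("no components survive the size/border filters",
                          call. = FALSE)
  list(mask = volume3d(out, rv$spacing, rv$origin), objects = objects)
}

empty_object_table <- function() {
  data.frame(id = integer(0), voxels = integer(0), centroid_z = numeric(0),
             centroid_y = numeric(0), centroid_x = numeric(0),
             border_flag = logical(0), kept = logical(0))
}
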