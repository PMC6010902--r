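#' Scalar 3-D volume with isotropic spacing
#'
#' `Volume3D` is the universal carrier of this package: phantoms, phase
#' reconstructions and label maps are all stored as a 3-D array of scalars
#' plus an isotropic voxel spacing in nanometres and a physical origin.
#'
#' Axis convention, used everywhere in the package: the array is indexed
#' `[z, y, x]` with the tomographic slice axis (z) first.  Voxel coordinates
#' reported by analysis functions (centroids, seeds, offsets) are 0-based
#' `(z, y, x)` triplets; R's 1-based array subscript for a voxel at
#' coordinate `c(z, y, x)` is `c(z, y, x) + 1`.
#'
#' @param voxels 3-D numeric (or integer, for label maps) array.
#' @param spacing voxel edge length in nm (single positive number; voxels are
#'   isotropic).
#' @param origin physical position of voxel (0,0,0), nm, length-3 `(z, y, x)`.
#' @return An object of class `Volume3D`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = 25)
#' dim(v)
#' @export
volume3d <- function(voxels, spacing = 1, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (nm per voxel)",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "Volume3D")
}

#' @export
dim.Volume3D <- function(x) dim(x$voxels)

#' @export
as.array.Volume3D <- function(x, ...) x$voxels

#' @export
print.Volume3D <- function(x, ...) {
  d <- dim(x$voxels)
  rng <- suppressWarnings(range(x$voxels, finite = TRUE))
  cat(sprintf("Volume3D  %d x %d x %d voxels (z,y,x), spacing %g nm\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  values in [%.4g, %.4g], origin (%g, %g, %g) nm\n",
              rng[1], rng[2], x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "Volume3D")

as_volume3d <- function(x, like = NULL, spacing = NULL, origin = NULL) {
  if (is_volume3d(x)) return(x)
  volume3d(x,
           spacing = if (!is.null(spacing)) spacing
                     else if (!is.null(like)) like$spacing else 1,
           origin = if (!is.null(origin)) origin
                    else if (!is.null(like)) like$origin else c(0, 0, 0))
}

#' Check that two volumes are geometrically congruent
#'
#' Congruent volumes share shape and spacing; label volumes produced by the
#' generators and segmenters are always congruent with their intensity
#' volumes.
#'
#' @param a,b `Volume3D` objects.
#' @return `TRUE` or `FALSE`.
#' @export
congruent <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

stopifnot_congruent <- function(a, b) {
  if (!congruent(a, b))
    stop("volumes are not congruent (shape/spacing mismatch)", call. = FALSE)
}

# run an expression with a local RNG stream seeded from `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Gaussian smoothing / derivatives of a 3-D array (sigma in voxels).
# orders is the derivative order along (z, y, x).
gaussian_filter3 <- function(arr, sigma, orders = c(0L, 0L, 0L),
                             truncate = 4) {
  d <- dim(arr)
  out <- cpp_gaussian_deriv(as.numeric(arr), as.integer(d), sigma,
                            as.integer(orders), truncate)
  array(out, d)
}
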