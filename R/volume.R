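#' 3D scalar image with voxel-to-world affine
#'
#' Minimal volume container used for coherence images, tract-density images,
#' masks and statistic maps. The affine maps 0-based voxel indices to world
#' millimetre coordinates (NIfTI convention).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is singular")
  structure(list(data = data, affine = affine), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<volume_image> %dx%dx%d voxels, voxel size %g x %g x %g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' Construct an axis-aligned affine from voxel size and origin
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @param origin World coordinate of voxel (1,1,1) (mm).
#' @return 4x4 affine.
#' @export
make_affine <- function(voxel_size, origin) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(voxel_size, 3, 3)
  a[1:3, 4] <- origin
  a
}

#' Symmetric toy volume template
#'
#' Axis-aligned image grid whose voxel-centre x coordinates are symmetric
#' about the world plane x = 0, so that a mid-sagittal flip is an exact
#' index permutation.
#'
#' @param extent_mm Half-extent of the box in mm (per axis).
#' @param voxel_size Isotropic voxel edge in mm (default 2).
#' @return A `volume_image` of zeros.
#' @export
symmetric_template <- function(extent_mm = 31, voxel_size = 2) {
  m <- ceiling(extent_mm / voxel_size - 0.5) + 1L
  # centres at +/-(0.5, 1.5, ..., m-0.5)*vs: symmetric pairs, none at 0
  origin <- -(m - 0.5) * voxel_size
  aff <- make_affine(rep(voxel_size, 3), rep(origin, 3))
  volume_image(array(0, dim = rep(2L * m, 3)), aff)
}

#' World coordinates of every voxel centre
#' @param img A `volume_image`.
#' @return n_voxels x 3 matrix (in array order) of world mm coordinates.
#' @export
voxel_centers <- function(img) {
  d <- dim(img$data)
  g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                             z = 0:(d[3] - 1)))
  sweep(g %*% t(img$affine[1:3, 1:3]), 2, img$affine[1:3, 4], "+")
}

#' Convert world mm points to (continuous, 1-based) voxel indices
#' @param img A `volume_image`.
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix of 1-based voxel indices (continuous).
#' @export
world_to_voxel <- function(img, pts) {
  pts <- matrix(pts, ncol = 3)
  inv <- solve(img$affine)
  v <- cbind(pts, 1) %*% t(inv)
  v[, 1:3, drop = FALSE] + 1
}

#' Mirror a volume across the mid-sagittal plane (world x = 0)
#'
#' The value at world point (x, y, z) becomes the value formerly at
#' (-x, y, z). On a grid whose voxel-centre x coordinates form a set
#' symmetric about 0 (see [symmetric_template()]) this is an exact index
#' permutation and the flip is an involution.
#'
#' @param img A `volume_image` with an axis-aligned affine.
#' @return The flipped `volume_image`.
#' @export
flip_midsagittal <- function(img) {
  a <- img$affine
  offdiag <- a[1:3, 1:3]; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-9))
    stop("flip_midsagittal requires an axis-aligned affine")
  d <- dim(img$data)
  xs <- a[1, 4] + (0:(d[1] - 1)) * a[1, 1]
  perm <- match(round(-xs, 6), round(xs, 6))
  if (anyNA(perm)) {
    # grid not exactly symmetric: nearest-neighbour mapping
    perm <- vapply(-xs, function(x) which.min(abs(xs - x)), integer(1))
  }
  out <- img
  out$data <- img$data[perm, , , drop = FALSE]
  out
}

.vox_linear <- function(d, ijk) {
  # 1-based i,j,k matrix -> linear index; NA when outside
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  lin <- rep(NA_integer_, nrow(ijk))
  lin[ok] <- (ijk[ok, 3] - 1L) * d[1] * d[2] + (ijk[ok, 2] - 1L) * d[1] +
    ijk[ok, 1]
  lin
}
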