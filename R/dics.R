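#' Source grid for beamformer imaging
#'
#' Regular lattice of candidate source locations inside a brain mask, with
#' uniform spacing and symmetry about the world plane x = 0 so that
#' mid-sagittal flipping maps grid points onto grid points.
#'
#' @param mask A binary `volume_image` defining the brain.
#' @param spacing Grid spacing in mm (default 5).
#' @return A `source_grid`: list with `points` (n x 3 world mm, ordered),
#'   `mask`, and `spacing`.
#' @export
make_source_grid <- function(mask, spacing = 5) {
  ctr <- voxel_centers(mask)
  lim <- apply(ctr, 2, range)
  ax <- lapply(1:3, function(k) {
    if (k == 1) {
      # symmetric about x = 0: +/- (0.5, 1.5, ...) * spacing
      m <- floor((lim[2, k] - spacing / 2) / spacing)
      s <- (0:m + 0.5) * spacing
      sort(c(-rev(s), s))
    } else {
      lo <- ceiling(lim[1, k] / spacing) * spacing
      seq(lo, lim[2, k], by = spacing)
    }
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  ijk <- round(world_to_voxel(mask, pts))
  lin <- .vox_linear(dim(mask$data), ijk)
  inside <- !is.na(lin) & mask$data[lin] > 0
  source_grid(pts[inside, , drop = FALSE], mask, spacing)
}

#' @rdname make_source_grid
#' @param points n x 3 matrix of world mm grid coordinates.
#' @export
source_grid <- function(points, mask, spacing) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 2) stop("source grid needs at least 2 points")
  if (anyDuplicated(round(points, 6))) stop("grid points must be distinct")
  # symmetry about x = 0
  key <- paste(round(-points[, 1], 4), round(points[, 2], 4),
               round(points[, 3], 4))
  have <- paste(round(points[, 1], 4), round(points[, 2], 4),
                round(points[, 3], 4))
  if (!all(key %in% have))
    warning("source grid is not symmetric about x = 0; ",
            "mid-sagittal flipping will interpolate")
  structure(list(points = points, mask = mask, spacing = spacing),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %g mm spacing\n",
              nrow(x$points), x$spacing))
  invisible(x)
}

#' DICS spatial filters
#'
#' Builds one beamformer weight vector per grid point from the band-averaged
#' sensor cross-spectral density: `w(g) = C^-1 l / (l' C^-1 l)` with
#' `C = Re(mean_band S) + lambda * mean(diag) * I` and `l` the leadfield row
#' of grid point `g` (scalar, orientation-free leadfield). Each filter has
#' unit gain at its own location, `w' l = 1`.
#'
#' @param csd Sensor-only `cross_spectrum`.
#' @param leadfield n_grid x n_sensors gain matrix.
#' @param grid A `source_grid` whose rows match `leadfield`.
#' @param band A `frequency_band` over which the CSD is averaged.
#' @param regularization Regularization as a fraction of the mean sensor
#'   power (default 0.05).
#' @return n_grid x n_sensors numeric matrix of filter weights.
#' @export
dics_filters <- function(csd, leadfield, grid, band, regularization = 0.05) {
  leadfield <- as.matrix(leadfield)
  if (nrow(leadfield) != nrow(grid$points))
    stop("leadfield rows must match grid points")
  if (ncol(leadfield) != length(csd$labels))
    stop("leadfield columns must match CSD channels")
  if (length(csd$labels) < 2) stop("need at least 2 sensors")
  if (regularization < 0) stop("regularization must be >= 0")
  sel <- csd$freqs >= band$lo & csd$freqs <= band$hi
  if (!any(sel)) stop("no CSD bins inside band ", band$name)
  Cb <- apply(csd$S[, , sel, drop = FALSE], c(1, 2), mean)
  C <- Re(Cb) + regularization * mean(Re(diag(Cb))) * diag(nrow(Cb))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("regularized sensor CSD is singular; increase regularization"))
  CiL <- leadfield %*% Ci                      # n_grid x n_sensors
  denom <- rowSums(CiL * leadfield)            # l' C^-1 l per grid point
  if (any(denom <= 0))
    stop("non-positive l' C^-1 l; increase regularization")
  W <- CiL / denom
  rownames(W) <- NULL
  W
}

#' Source-reference coherence image
#'
#' Applies DICS filters to the band-averaged cross-spectral density
#' (sensors + reference channel) to image magnitude-squared coherence
#' between each grid source and the reference:
#' `|w' S_xr|^2 / ((w' S_xx w) S_rr)`. Grid values are then interpolated
#' (trilinear, mask-clipped) onto the 2 mm voxel lattice of the grid's mask.
#'
#' @param csd `cross_spectrum` over sensors plus the reference channel.
#' @param filters Matrix from [dics_filters()] (computed without the
#'   reference channel).
#' @param grid The `source_grid` used for the filters.
#' @param band A `frequency_band`.
#' @param reference Label of the reference (LFP) channel in `csd`.
#' @return A `coherence_image`: `volume_image` with values in `[0, 1]`
#'   inside the mask, `NA` outside, plus `band` and `reference` fields.
#' @export
coherence_image <- function(csd, filters, grid, band, reference = "LFP") {
  ri <- match(reference, csd$labels)
  if (is.na(ri)) stop("reference channel not present in CSD")
  si <- setdiff(seq_along(csd$labels), ri)
  if (ncol(filters) != length(si))
    stop("filter width must equal the number of non-reference channels")
  sel <- csd$freqs >= band$lo & csd$freqs <= band$hi
  if (!any(sel)) stop("no CSD bins inside band ", band$name)
  Sb <- apply(csd$S[, , sel, drop = FALSE], c(1, 2), mean)
  srr <- Re(Sb[ri, ri])
  if (srr <= 0) stop("reference auto-spectrum is zero in band ", band$name)
  Sss <- Sb[si, si]
  sxr <- Sb[si, ri]
  num <- Mod(Conj(filters) %*% sxr)^2                   # |w^H S_xr|^2
  WS <- Conj(filters) %*% Sss                           # w^H S_ss
  den <- Re(rowSums(WS * filters)) * srr                # (w^H S w) S_rr
  vals <- pmin(pmax(as.vector(num / den), 0), 1)
  img <- .grid_to_image(vals, grid)
  img$band <- band
  img$reference <- reference
  class(img) <- c("coherence_image", class(img))
  img
}

# trilinear interpolation of grid-point values onto the mask voxel lattice
.grid_to_image <- function(vals, grid) {
  ax <- lapply(1:3, function(k) sort(unique(grid$points[, k])))
  ga <- array(NA_real_, dim = vapply(ax, length, integer(1)))
  gi <- cbind(match(grid$points[, 1], ax[[1]]),
              match(grid$points[, 2], ax[[2]]),
              match(grid$points[, 3], ax[[3]]))
  ga[gi] <- vals
  # fill undefined lattice nodes with nearest defined value (axis-wise sweep)
  if (anyNA(ga)) ga <- .fill_na_nearest(ga, ax, grid$points, vals)
  mask <- grid$mask
  ctr <- voxel_centers(mask)
  out <- rep(NA_real_, nrow(ctr))
  inside <- as.logical(mask$data > 0)
  p <- ctr[inside, , drop = FALSE]
  # continuous position on the grid lattice
  u <- lapply(1:3, function(k) {
    a <- ax[[k]]
    x <- (p[, k] - a[1]) / (a[2] - a[1])
    pmin(pmax(x, 0), length(a) - 1)
  })
  d <- dim(ga)
  i0 <- lapply(1:3, function(k) pmin(floor(u[[k]]), d[k] - 2) + 1)
  fr <- lapply(1:3, function(k) u[[k]] - (i0[[k]] - 1))
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[[1]] else 1 - fr[[1]]) *
         (if (dy) fr[[2]] else 1 - fr[[2]]) *
         (if (dz) fr[[3]] else 1 - fr[[3]])
    idx <- cbind(i0[[1]] + dx, i0[[2]] + dy, i0[[3]] + dz)
    acc <- acc + w * ga[idx]
  }
  out[inside] <- acc
  volume_image(array(out, dim = dim(mask$data)), mask$affine)
}

.fill_na_nearest <- function(ga, ax, pts, vals) {
  nas <- which(is.na(ga), arr.ind = TRUE)
  if (!nrow(nas)) return(ga)
  co <- cbind(ax[[1]][nas[, 1]], ax[[2]][nas[, 2]], ax[[3]][nas[, 3]])
  key <- order(pts[, 1], pts[, 2], pts[, 3])   # order-independent tie-break
  for (r in seq_len(nrow(nas))) {
    dd <- colSums((t(pts) - co[r, ])^2)
    cand <- which(dd <= min(dd) + 1e-9)
    pick <- cand[which.min(match(cand, key))]
    ga[nas[r, 1], nas[r, 2], nas[r, 3]] <- vals[pick]
  }
  ga
}
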