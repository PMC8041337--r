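#' Streamline set
#'
#' Collection of polylines in world mm coordinates with per-streamline
#' identity.
#'
#' @param streamlines List of n x 3 numeric matrices (vertices, world mm).
#' @param ids Optional identifiers; default sequential integers.
#' @return A `streamline_set`.
#' @export
streamline_set <- function(streamlines, ids = seq_along(streamlines)) {
  streamlines <- lapply(streamlines, function(m) {
    m <- matrix(as.numeric(m), ncol = 3)
    if (nrow(m) < 1) stop("each streamline needs at least one vertex")
    m
  })
  if (length(ids) != length(streamlines)) stop("ids length mismatch")
  structure(list(streamlines = streamlines, ids = ids),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  nv <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat(sprintf("<streamline_set> %d streamlines, %d vertices\n",
              length(x$streamlines), nv))
  invisible(x)
}

#' Number of streamlines
#' @param s A `streamline_set`.
#' @export
n_streamlines <- function(s) length(s$streamlines)

#' Spherical seed region of interest
#'
#' Models the seed used for fibre selection: a sphere centred at the
#' midpoint of a contact pair with a radius that just encompasses it,
#' combined with a binary mask of the structure of interest that retained
#' fibres must also traverse.
#'
#' @param center World mm centre of the sphere.
#' @param radius Sphere radius in mm (> 0).
#' @param structure_mask Binary `volume_image`; retained streamlines must
#'   intersect a nonzero voxel.
#' @return A `seed_roi`.
#' @export
seed_roi <- function(center, radius, structure_mask) {
  if (radius <= 0) stop("radius must be > 0")
  u <- unique(as.vector(structure_mask$data))
  if (!all(u %in% c(0, 1))) stop("structure_mask must be binary")
  structure(list(center = as.numeric(center), radius = radius,
                 structure_mask = structure_mask), class = "seed_roi")
}

# resample a polyline so consecutive vertices are at most `step` mm apart
.densify <- function(m, step = 0.5) {
  if (nrow(m) == 1) return(m)
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  if (all(seg <= step)) return(m)
  pieces <- vector("list", nrow(m) - 1)
  for (i in seq_len(nrow(m) - 1)) {
    k <- max(1L, ceiling(seg[i] / step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    pieces[[i]] <- cbind(m[i, 1] + t * (m[i + 1, 1] - m[i, 1]),
                         m[i, 2] + t * (m[i + 1, 2] - m[i, 2]),
                         m[i, 3] + t * (m[i + 1, 3] - m[i, 3]))
  }
  rbind(do.call(rbind, pieces), m[nrow(m), , drop = FALSE])
}

#' Filter streamlines by seed sphere and structure mask
#'
#' Retains streamlines that (a) pass within `roi$radius` of `roi$center`
#' and (b) intersect at least one nonzero voxel of `roi$structure_mask`.
#' Both criteria are judged on the polyline densified to steps of at most
#' 0.5 mm, matching the traversal logic of [density_image()].
#'
#' @param s A `streamline_set`.
#' @param roi A [seed_roi()].
#' @return The filtered `streamline_set`.
#' @export
filter_streamlines <- function(s, roi) {
  stopifnot(inherits(s, "streamline_set"), inherits(roi, "seed_roi"))
  if (n_streamlines(s) == 0) {
    warning("empty streamline set")
    return(s)
  }
  msk <- roi$structure_mask
  d <- dim(msk$data)
  keep <- vapply(s$streamlines, function(m) {
    dm <- .densify(m, 0.5)
    d2 <- colSums((t(dm) - roi$center)^2)
    if (min(d2) > roi$radius^2) return(FALSE)
    ijk <- round(world_to_voxel(msk, dm))
    lin <- .vox_linear(d, ijk)
    lin <- lin[!is.na(lin)]
    length(lin) > 0 && any(msk$data[lin] > 0)
  }, logical(1))
  streamline_set(s$streamlines[keep], s$ids[keep])
}

#' Voxel-wise tract density of a streamline set
#'
#' Counts, in each voxel of the template lattice, the number of streamlines
#' that traverse it: each streamline increments each voxel it passes
#' through by exactly one, regardless of in-voxel path length or repeated
#' visits (binary-per-streamline rule). Traversal is judged on the polyline
#' densified to steps of at most 0.5 mm.
#'
#' @param s A `streamline_set` (already seed-filtered, if applicable).
#' @param template A `volume_image` defining the output lattice (typically
#'   2 mm isotropic).
#' @return A `volume_image` of nonnegative integer counts.
#' @export
density_image <- function(s, template) {
  stopifnot(inherits(s, "streamline_set"), inherits(template, "volume_image"))
  d <- dim(template$data)
  counts <- array(0L, d)
  for (m in s$streamlines) {
    dm <- .densify(m, 0.5)
    ijk <- round(world_to_voxel(template, dm))
    lin <- unique(.vox_linear(d, ijk))
    lin <- lin[!is.na(lin)]
    counts[lin] <- counts[lin] + 1L
  }
  volume_image(counts, template$affine)
}

#' Group comparison of tract-density images (2 x 2 ANOVA with covariates)
#'
#' Mass-univariate ordinary-least-squares two-factor model per voxel:
#' effect-coded contact location and disease factors, their interaction, an
#' effect-coded side covariate, and subject covariates (sum-to-zero within
#' each disease group, so the between-subject disease effect stays
#' estimable). Each requested effect is tested with a partial F
#' (model-comparison) statistic and inference uses the cluster-based
#' permutation engine, permuting the effect's labels within subject (for
#' within-subject effects) or across subjects (for disease).
#'
#' @param images List of co-registered `volume_image` tract densities, one
#'   per observation.
#' @param location Factor/character of contact location per observation
#'   (two levels, e.g. NBM vs GP).
#' @param disease Factor/character of disease per observation (two levels).
#' @param subject Subject identifier per observation.
#' @param side Recording side per observation (two levels).
#' @param effect Which effect to test: `"location"`, `"disease"` or
#'   `"interaction"`.
#' @param mask Binary `volume_image`; defaults to voxels with any nonzero
#'   density.
#' @param forming_p Cluster-forming threshold as an upper-tail p (default
#'   0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutation engine.
#' @return List with `F_image`, `T_image` (signed, for 1-df contrasts),
#'   `df`, `clusters` (a `cluster_result`) and the design matrix used.
#' @export
density_anova <- function(images, location, disease, subject, side,
                          effect = c("location", "disease", "interaction"),
                          mask = NULL, forming_p = 0.01, n_perm = 1000,
                          seed = 1) {
  effect <- match.arg(effect)
  n <- length(images)
  .check_same_geometry(images)
  location <- as.factor(location); disease <- as.factor(disease)
  subject <- as.factor(subject); side <- as.factor(side)
  if (nlevels(location) != 2 || nlevels(disease) != 2)
    stop("location and disease must each have exactly two levels")
  if (min(table(location, disease)) < 2)
    stop("need at least 2 observations per design cell")
  d <- dim(images[[1]]$data)
  if (is.null(mask)) {
    any_nz <- Reduce(`+`, lapply(images, function(im) (im$data > 0) * 1))
    mask <- volume_image(array(as.numeric(any_nz > 0), d),
                         images[[1]]$affine)
  }
  vox <- which(mask$data > 0)
  Y <- vapply(images, function(im) im$data[vox], numeric(length(vox)))
  Y <- t(Y)                                              # n_obs x n_vox

  loc_c <- ifelse(location == levels(location)[1], 1, -1)
  dis_c <- ifelse(disease == levels(disease)[1], 1, -1)
  side_c <- ifelse(side == levels(side)[1], 1, -1)
  subj_cols <- .subject_deviation_columns(subject, disease)
  X_full <- cbind(intercept = 1, location = loc_c, disease = dis_c,
                  interaction = loc_c * dis_c, side = side_c, subj_cols)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  test_col <- match(effect, colnames(X_full))
  df_err <- n - qr_full$rank

  stat_fun <- function(Yp) {
    fit <- .ols_partial_f(X_full, Yp, test_col)
    fit
  }
  obs <- stat_fun(Y)
  thr <- stats::qf(1 - forming_p, 1, df_err)
  perm_blocks <- if (effect == "disease") NULL else subject
  set.seed(seed)
  perm_max <- numeric(n_perm)
  for (pi in seq_len(n_perm)) {
    ord <- .block_permutation(n, perm_blocks)
    Fp <- stat_fun(Y[ord, , drop = FALSE])$F
    perm_max[pi] <- .max_cluster_size(Fp > thr, vox, d)
  }
  clusters <- .build_cluster_result(obs$F, thr, vox, d, perm_max, n_perm,
                                    forming_p, mask$affine)
  Fimg <- array(NA_real_, d); Fimg[vox] <- obs$F
  Timg <- array(NA_real_, d); Timg[vox] <- obs$t
  list(F_image = volume_image(Fimg, mask$affine),
       T_image = volume_image(Timg, mask$affine),
       df = c(1, df_err), clusters = clusters, design = X_full,
       effect = effect)
}

# subject indicator columns, sum-to-zero within each disease group, so the
# between-subject disease contrast is not aliased
.subject_deviation_columns <- function(subject, disease) {
  cols <- NULL
  for (g in levels(disease)) {
    subj_g <- unique(as.character(subject[disease == g]))
    if (length(subj_g) < 2) next
    for (s in subj_g[-length(subj_g)]) {
      v <- ifelse(as.character(subject) == s, 1,
                  ifelse(as.character(subject) == subj_g[length(subj_g)],
                         -1, 0))
      v[disease != g] <- 0
      cols <- cbind(cols, v)
    }
  }
  if (!is.null(cols))
    colnames(cols) <- paste0("subj", seq_len(ncol(cols)))
  cols
}

# partial F (and signed t) for a single column of X against Y (n x V)
.ols_partial_f <- function(X, Y, test_col) {
  qr_f <- qr(X)
  res_f <- qr.resid(qr_f, Y)
  rss_f <- colSums(res_f^2)
  qr_r <- qr(X[, -test_col, drop = FALSE])
  rss_r <- colSums(qr.resid(qr_r, Y)^2)
  df_err <- nrow(X) - qr_f$rank
  Fv <- (rss_r - rss_f) / (rss_f / df_err)
  Fv[Fv < 0] <- 0
  beta <- qr.coef(qr_f, Y)[test_col, ]
  list(F = Fv, t = sign(beta) * sqrt(Fv))
}

.block_permutation <- function(n, blocks) {
  if (is.null(blocks)) return(sample.int(n))
  ord <- seq_len(n)
  for (b in unique(blocks)) {
    ii <- which(blocks == b)
    ord[ii] <- ii[sample.int(length(ii))]
  }
  ord
}
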