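#' Upper-tail p-value of the central F distribution
#'
#' Maps an F statistic with (df1, df2) degrees of freedom to its upper-tail
#' probability. Used for cluster-forming thresholds and for the paired
#' time-reversal test reported as `F = t^2` with df (1, n - 1).
#'
#' @param f F statistic (>= 0), vectorized.
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
f_tail_p <- function(f, df1, df2) {
  if (any(f < 0)) stop("F statistic must be nonnegative")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Voxel-wise GLM with voxel-specific design matrices
#'
#' The core structure-function statistic: for every voxel `v`, coherence
#' across observations is regressed on tract density at the same voxel,
#' `coherence_i(v) = b0 + b1 density_i(v) + e_i`. Because the regressor is
#' an image, the design matrix differs per voxel (unlike the classical
#' mass-univariate GLM, which this reduces to when all voxels share one
#' density column). The slope is tested with an F statistic on
#' (1, n - 2) degrees of freedom.
#'
#' Voxels whose density has zero variance across observations are
#' undefined (excluded from clustering). Voxels fitting exactly (zero
#' residual sum of squares) are assigned the largest finite F and flagged.
#'
#' @param coherence_imgs List of co-registered `volume_image` coherence
#'   images (dependent variable), one per observation.
#' @param density_imgs List of co-registered `volume_image` tract-density
#'   images (independent variable), same order.
#' @param mask Binary `volume_image`; defaults to voxels where all
#'   coherence images are finite.
#' @param fisher_z If `TRUE`, coherence values are variance-stabilized with
#'   `atanh(sqrt(coh))` before fitting (off by default).
#' @return A `voxel_glm_result` with `F_image`, `beta_image`, `df`,
#'   `exact_fit` flags, the mask, and the data matrices needed by
#'   [cluster_permutation()].
#' @export
voxelwise_sfc_glm <- function(coherence_imgs, density_imgs, mask = NULL,
                              fisher_z = FALSE) {
  n <- length(coherence_imgs)
  if (length(density_imgs) != n)
    stop("coherence and density image lists must have equal length")
  if (n < 4) stop("need at least 4 observations")
  .check_same_geometry(c(coherence_imgs, density_imgs))
  d <- dim(coherence_imgs[[1]]$data)
  aff <- coherence_imgs[[1]]$affine
  if (is.null(mask)) {
    fin <- Reduce(`+`, lapply(coherence_imgs,
                              function(im) is.finite(im$data) * 1))
    mask <- volume_image(array(as.numeric(fin == n), d), aff)
  }
  vox <- which(mask$data > 0)
  if (!length(vox)) stop("empty mask")
  Y <- t(vapply(coherence_imgs, function(im) im$data[vox],
                numeric(length(vox))))
  X <- t(vapply(density_imgs, function(im) im$data[vox],
                numeric(length(vox))))
  if (fisher_z) Y <- atanh(sqrt(pmin(pmax(Y, 0), 1 - 1e-12)))
  fit <- .simple_reg_f(X, Y)
  if (all(is.na(fit$F))) stop("density is constant across observations at every voxel")
  Fimg <- array(NA_real_, d); Fimg[vox] <- fit$F
  Bimg <- array(NA_real_, d); Bimg[vox] <- fit$beta
  structure(list(F_image = volume_image(Fimg, aff),
                 beta_image = volume_image(Bimg, aff),
                 df = c(1, n - 2),
                 exact_fit = {e <- array(FALSE, d); e[vox] <- fit$exact; e},
                 mask = mask, vox = vox, Y = Y, X = X,
                 defined = fit$defined),
            class = "voxel_glm_result")
}

#' @export
print.voxel_glm_result <- function(x, ...) {
  cat(sprintf(
    "<voxel_glm_result> %d voxels (%d defined), df (%d, %d), max F %.2f\n",
    length(x$vox), sum(x$defined), x$df[1], x$df[2],
    suppressWarnings(max(x$F_image$data, na.rm = TRUE))))
  invisible(x)
}

# vectorized per-voxel simple regression of Y on X (both n x V)
.simple_reg_f <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- colSums(Xc^2)
  syy <- colSums(Yc^2)
  sxy <- colSums(Xc * Yc)
  defined <- sxx > 1e-12 * pmax(1, colMeans(X)^2) & sxx > 0
  beta <- ifelse(defined, sxy / sxx, NA_real_)
  ess <- ifelse(defined, sxy^2 / sxx, NA_real_)
  rss <- syy - ess
  exact <- defined & rss <= 1e-12 * pmax(syy, 1e-300)
  Fv <- ess / (rss / (n - 2))
  Fv[exact] <- .Machine$double.xmax
  Fv[!defined] <- NA_real_
  Fv[defined & !exact & Fv < 0] <- 0
  list(F = Fv, beta = beta, exact = exact, defined = defined)
}

.check_same_geometry <- function(imgs) {
  d0 <- dim(imgs[[1]]$data); a0 <- imgs[[1]]$affine
  for (im in imgs[-1]) {
    if (!identical(dim(im$data), d0)) stop("image shapes differ")
    if (max(abs(im$affine - a0)) > 1e-6) stop("image affines differ")
  }
  invisible(TRUE)
}

#' Cluster-based permutation inference for the voxel-wise GLM
#'
#' Thresholds the observed F image at the `1 - forming_p` quantile of
#' F(df), labels suprathreshold clusters (26-connectivity, restricted to
#' defined voxels), and builds the null distribution of the maximal
#' cluster extent by permuting the assignment of coherence observations
#' against density observations - the same permutation at every voxel, so
#' spatial correlation is preserved. Family-wise error p of a cluster of
#' size s is `(1 + #{perm max >= s}) / (1 + n_perm)`, which includes the
#' identity permutation and is therefore never below `1/(1 + n_perm)`.
#'
#' @param result A `voxel_glm_result`.
#' @param forming_p Cluster-forming threshold as an upper-tail p
#'   (default 0.01).
#' @param n_perm Number of permutations (>= 100, default 1000).
#' @param seed RNG seed for reproducible permutations.
#' @return A `cluster_result`: `label_image`, `table` (label, size, peak F,
#'   peak world mm coordinate, FWE p), `threshold`, `perm_max_sizes`.
#' @export
cluster_permutation <- function(result, forming_p = 0.01, n_perm = 1000,
                                seed = 1) {
  stopifnot(inherits(result, "voxel_glm_result"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (forming_p <= 0 || forming_p >= 1) stop("forming_p must be in (0, 1)")
  d <- dim(result$mask$data)
  thr <- stats::qf(1 - forming_p, result$df[1], result$df[2])
  X <- result$X; Y <- result$Y
  n <- nrow(X)
  set.seed(seed)
  perm_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Fp <- .simple_reg_f(X, Y[sample.int(n), , drop = FALSE])$F
    perm_max[p] <- .max_cluster_size(Fp > thr & result$defined,
                                     result$vox, d)
  }
  Fobs <- result$F_image$data[result$vox]
  Fobs[!result$defined] <- NA_real_
  .build_cluster_result(Fobs, thr, result$vox, d, perm_max, n_perm,
                        forming_p, result$mask$affine)
}

.build_cluster_result <- function(Fvals, thr, vox, d, perm_max, n_perm,
                                  forming_p, affine) {
  supra <- array(FALSE, d)
  supra[vox[which(Fvals > thr)]] <- TRUE
  lab <- label_components_26(supra)
  nclus <- max(lab)
  tab <- data.frame(label = integer(0), size = integer(0),
                    peak_F = numeric(0), peak_x = numeric(0),
                    peak_y = numeric(0), peak_z = numeric(0),
                    p_fwe = numeric(0))
  if (nclus > 0) {
    Fimg <- array(NA_real_, d); Fimg[vox] <- Fvals
    for (cl in seq_len(nclus)) {
      ii <- which(lab == cl)
      size <- length(ii)
      peak <- ii[which.max(Fimg[ii])]
      ijk <- .lin_to_ijk(peak, d)
      wc <- as.numeric(affine %*% c(ijk - 1, 1))[1:3]
      pfwe <- (1 + sum(perm_max >= size)) / (1 + n_perm)
      tab <- rbind(tab, data.frame(label = cl, size = size,
                                   peak_F = Fimg[peak], peak_x = wc[1],
                                   peak_y = wc[2], peak_z = wc[3],
                                   p_fwe = pfwe))
    }
    tab <- tab[order(tab$size, decreasing = TRUE), ]
    rownames(tab) <- NULL
  }
  structure(list(label_image = volume_image(lab, affine), table = tab,
                 threshold = thr, forming_p = forming_p,
                 n_perm = n_perm, perm_max_sizes = perm_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), forming threshold F > %.3f, %d permutations\n",
    nrow(x$table), x$threshold, x$n_perm))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

.max_cluster_size <- function(supra_vals, vox, d) {
  if (!any(supra_vals, na.rm = TRUE)) return(0)
  supra <- array(FALSE, d)
  supra[vox[which(supra_vals)]] <- TRUE
  lab <- label_components_26(supra)
  if (max(lab) == 0) return(0)
  max(tabulate(lab[lab > 0]))
}

#' Label connected components of a 3D logical array (26-connectivity)
#'
#' @param mask 3D logical array.
#' @return Integer array of the same shape; 0 outside components,
#'   1..n_components inside.
#' @export
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  # 26-neighbour linear offsets
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  ijk <- cbind((idx - 1L) %% d[1],
               ((idx - 1L) %/% d[1]) %% d[2],
               (idx - 1L) %/% (d[1] * d[2])) + 1L
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  cur <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    cur <- cur + 1L
    queue <- idx[s]
    lab[idx[s]] <- cur
    qi <- cbind(ijk[s, 1], ijk[s, 2], ijk[s, 3])
    frontier <- qi
    while (nrow(frontier) > 0) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                       drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- (cand[, 3] - 1L) * d[1] * d[2] + (cand[, 2] - 1L) * d[1] +
        cand[, 1]
      keep <- !duplicated(lin)
      cand <- cand[keep, , drop = FALSE]; lin <- lin[keep]
      new <- inmask[lin] & lab[lin] == 0L
      if (!any(new)) break
      lab[lin[new]] <- cur
      frontier <- cand[new, , drop = FALSE]
    }
  }
  lab
}
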