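#' Simulate a stationary vector autoregressive process
#'
#' Oracle substrate for the spectral Granger machinery: simulates
#' `x_t = sum_l A_l x_{t-l} + e_t` with Gaussian innovations, discarding a
#' burn-in so the returned realization is (approximately) stationary.
#' `A_l[i, j]` is the influence of channel `j` at lag `l` on channel `i`.
#'
#' @param coeffs Coefficient array of dim `(order, k, k)`.
#' @param noise_cov `k x k` symmetric positive definite innovation covariance.
#' @param n_samples Number of samples to return.
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @param fs Nominal sampling rate attached to the recording (default 1).
#' @param burn_in Samples discarded before recording starts; at least
#'   10x the model order (default `max(500, 20 * order)`).
#' @return A `ts_recording` with `k` channels.
#' @export
simulate_var_sources <- function(coeffs, noise_cov, n_samples, seed,
                                 fs = 1, burn_in = NULL) {
  if (length(dim(coeffs)) != 3) stop("coeffs must be an (order, k, k) array")
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  if (dim(coeffs)[3] != k) stop("coeffs must be square in channels")
  noise_cov <- as.matrix(noise_cov)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-10)))
    stop("noise_cov must be symmetric")
  ch <- tryCatch(chol(noise_cov), error = function(e)
    stop("noise_cov is not positive definite"))
  # companion-matrix stability check
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[1:k, (l - 1) * k + 1:k] <- coeffs[l, , ]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable VAR: companion spectral radius %.4f >= 1", rho))
  if (is.null(burn_in)) burn_in <- max(500L, 20L * p)
  if (burn_in < 10 * p) stop("burn_in must be at least 10x the order")
  ntot <- n_samples + burn_in
  set.seed(seed)
  e <- matrix(stats::rnorm(ntot * k), ncol = k) %*% ch
  x <- matrix(0, ntot, k)
  A <- lapply(seq_len(p), function(l) t(coeffs[l, , , drop = TRUE]))
  if (k == 1) A <- lapply(seq_len(p), function(l) matrix(coeffs[l, 1, 1]))
  for (t in (p + 1):ntot) {
    acc <- e[t, ]
    for (l in seq_len(p)) acc <- acc + x[t - l, ] %*% A[[l]]
    x[t, ] <- acc
  }
  recording(x[(burn_in + 1):ntot, , drop = FALSE], fs,
            paste0("var", seq_len(k)))
}

#' Analytic spectral matrix of a VAR process
#'
#' `S(f) = A(f)^-1 Sigma A(f)^-H` with
#' `A(f) = I - sum_l A_l exp(-2 pi i f l / fs)`; the per-sample two-sided
#' spectral density whose mean over the full frequency circle equals the
#' process covariance.
#'
#' @inheritParams simulate_var_sources
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return `k x k x length(freqs)` complex array.
#' @export
var_spectral_matrix <- function(coeffs, noise_cov, freqs, fs) {
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  S <- array(0 + 0i, dim = c(k, k, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(k) + 0i
    for (l in seq_len(p))
      Af <- Af - matrix(coeffs[l, , ], k, k) * exp(-2i * pi * freqs[fi] * l / fs)
    H <- solve(Af)
    S[, , fi] <- H %*% noise_cov %*% Conj(t(H))
  }
  S
}

#' Analytic VAR cross-spectrum in the package's CSD convention
#'
#' Evaluates [var_spectral_matrix()] on a uniform grid from 0 to Nyquist
#' and packages it as a `cross_spectrum` (one-sided, interior bins doubled,
#' diagonal summing to the channel variance), so exact spectra can be fed
#' to the estimators in place of data-derived ones.
#'
#' @inheritParams var_spectral_matrix
#' @param n_freq Number of bins from 0 to Nyquist inclusive.
#' @return A `cross_spectrum`.
#' @export
var_csd <- function(coeffs, noise_cov, n_freq, fs) {
  freqs <- seq(0, fs / 2, length.out = n_freq)
  Sp <- var_spectral_matrix(coeffs, noise_cov, freqs, fs)
  M <- 2 * (n_freq - 1)
  S <- Sp / M
  if (n_freq > 2) S[, , 2:(n_freq - 1)] <- 2 * S[, , 2:(n_freq - 1)]
  k <- dim(coeffs)[2]
  structure(list(freqs = freqs, S = S, n_avg = 1L,
                 labels = paste0("var", seq_len(k)), fs = fs),
            class = "cross_spectrum")
}

#' Parametric spectral Granger causality of a known bivariate VAR
#'
#' Closed-form Geweke spectral measure computed from the true coefficients
#' (transfer function `H(f) = A(f)^-1`), used as an independent oracle for
#' the nonparametric (factorization-based) estimator.
#'
#' @inheritParams var_spectral_matrix
#' @return List with `freqs`, `gc_xy` (channel 1 -> 2) and `gc_yx`
#'   (channel 2 -> 1), each a nonnegative spectrum.
#' @export
var_granger_analytic <- function(coeffs, noise_cov, freqs, fs) {
  k <- dim(coeffs)[2]
  if (k != 2) stop("analytic Granger oracle is bivariate only")
  p <- dim(coeffs)[1]
  H <- array(0 + 0i, dim = c(2, 2, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (l in seq_len(p))
      Af <- Af - matrix(coeffs[l, , ], 2, 2) * exp(-2i * pi * freqs[fi] * l / fs)
    H[, , fi] <- solve(Af)
  }
  .geweke_bivariate(H, as.matrix(noise_cov), freqs)
}

# Geweke spectral measure from a transfer function and innovation
# covariance (closed form; used by the parametric oracle)
.geweke_bivariate <- function(H, Sg, freqs) {
  nf <- length(freqs)
  gc_xy <- numeric(nf); gc_yx <- numeric(nf)
  sig_y_x <- Sg[2, 2] - Sg[1, 2]^2 / Sg[1, 1]
  sig_x_y <- Sg[1, 1] - Sg[1, 2]^2 / Sg[2, 2]
  for (f in seq_len(nf)) {
    Hf <- H[, , f]
    R <- Hf %*% Sg %*% Conj(t(Hf))
    Htxy <- Hf[1, 2] + (Sg[1, 2] / Sg[1, 1]) * Hf[1, 1]
    Htyx <- Hf[2, 1] + (Sg[1, 2] / Sg[2, 2]) * Hf[2, 2]
    gc_yx[f] <- log(Re(R[1, 1]) / (Re(R[1, 1]) - sig_y_x * Mod(Htxy)^2))
    gc_xy[f] <- log(Re(R[2, 2]) / (Re(R[2, 2]) - sig_x_y * Mod(Htyx)^2))
  }
  list(freqs = freqs, gc_xy = gc_xy, gc_yx = gc_yx)
}

#' Inverse-distance toy leadfield
#'
#' Forward gain from each grid source to each sensor with an
#' inverse-square-distance profile, each row normalized to unit Euclidean
#' norm. A stand-in forward model for synthetic studies; no head geometry
#' is modelled.
#'
#' @param grid_points n_grid x 3 world mm source coordinates (distinct).
#' @param sensors n_sensors x 3 world mm sensor coordinates (>= 8).
#' @return n_grid x n_sensors gain matrix with unit-norm rows.
#' @export
make_toy_leadfield <- function(grid_points, sensors) {
  grid_points <- matrix(grid_points, ncol = 3)
  sensors <- matrix(sensors, ncol = 3)
  if (anyDuplicated(round(grid_points, 9))) stop("grid points must be distinct")
  if (nrow(sensors) < 8) stop("need at least 8 sensors")
  L <- matrix(0, nrow(grid_points), nrow(sensors))
  for (g in seq_len(nrow(grid_points))) {
    d2 <- colSums((t(sensors) - grid_points[g, ])^2)
    if (any(d2 < 1e-12))
      stop("grid point ", g, " coincides with a sensor")
    row <- 1 / d2
    L[g, ] <- row / sqrt(sum(row^2))
  }
  L
}

#' Sensor positions on a sphere
#'
#' Quasi-uniform (Fibonacci lattice) sensor array on the upper part of a
#' sphere, a toy analogue of a whole-head sensor layout.
#'
#' @param n Number of sensors.
#' @param radius Sphere radius in mm (default 80).
#' @return n x 3 matrix of world mm coordinates.
#' @export
toy_sensor_array <- function(n = 24, radius = 80) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 1.2 * i / n)            # mostly upper hemisphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = radius * sin(phi) * cos(theta),
        y = radius * sin(phi) * sin(theta),
        z = radius * cos(phi))
}

#' Spherical toy brain mask on a symmetric voxel grid
#' @param radius_mm Brain sphere radius (default 28 mm).
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @return Binary `volume_image` (1 inside the sphere).
#' @export
toy_brain_mask <- function(radius_mm = 28, voxel_size = 2) {
  tpl <- symmetric_template(radius_mm + voxel_size, voxel_size)
  ctr <- voxel_centers(tpl)
  inside <- rowSums(ctr^2) <= radius_mm^2
  tpl$data[] <- as.numeric(inside)
  tpl
}

#' Specification of one simulated coherent source
#'
#' @param location Grid-point index of the source.
#' @param band A `frequency_band` for the source oscillation.
#' @param coherence_target Intended magnitude-squared coherence with the
#'   reference channel, in `[0, 1]`.
#' @param direction One of `"source_drives_ref"`, `"ref_drives_source"`,
#'   `"bidirectional"`, `"none"`.
#' @param coupling_lag Coupling delay in samples (>= 1 unless direction is
#'   `"none"`).
#' @return A `source_spec`.
#' @export
source_spec <- function(location, band, coherence_target,
                        direction = c("none", "source_drives_ref",
                                      "ref_drives_source", "bidirectional"),
                        coupling_lag = 0L) {
  direction <- match.arg(direction)
  if (coherence_target < 0 || coherence_target > 1)
    stop("coherence_target must be in [0, 1]")
  if (direction != "none" && coupling_lag < 1)
    stop("coupling_lag must be >= 1 when direction != 'none'")
  structure(list(location = as.integer(location), band = band,
                 coherence_target = coherence_target, direction = direction,
                 coupling_lag = as.integer(coupling_lag)),
            class = "source_spec")
}

.bandpass <- function(x, band, fs) {
  ny <- fs / 2
  if (band$hi >= ny) stop("band upper edge ", band$hi,
                          " Hz is at or above Nyquist (", ny, " Hz)")
  bf <- signal::butter(4, c(band$lo, band$hi) / ny, type = "pass")
  y <- signal::filtfilt(bf, x)
  y / stats::sd(y)
}

.highpass1 <- function(x, fs) {
  bf <- signal::butter(4, 1 / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

.lagged <- function(x, lag, n) {
  # value at time t is x[t - lag]; x has length n + pad, pad >= lag
  pad <- length(x) - n
  x[seq_len(n) + pad - lag]
}

#' Generate one subject's synthetic recording
#'
#' Band-limited filtered-noise sources, each sharing an innovation with the
#' reference channel at a controlled lag so both the magnitude-squared
#' coherence and the direction of Granger causality are known by
#' construction. Sources are projected to the sensors through a leadfield
#' and independent Gaussian sensor noise is added at the requested SNR. The
#' reference channel is high-pass filtered at 1 Hz (4th-order zero-phase
#' Butterworth) before output, mirroring hardware filtering of intracranial
#' amplifiers without the phase distortion that would corrupt directionality
#' ground truth.
#'
#' @param spec List of [source_spec()] objects (possibly empty).
#' @param leadfield n_grid x n_sensors gain matrix; source locations index
#'   its rows.
#' @param duration_s Recording duration in seconds (default 180).
#' @param fs Sampling rate in Hz (default 300).
#' @param sensor_snr Ratio of projected-source variance to sensor-noise
#'   variance, averaged over sensors (`Inf` for noiseless sensors).
#' @param seed Integer RNG seed.
#' @param ref_label Label of the reference channel (default `"LFP"`).
#' @param ref_noise_sd Standard deviation of broadband noise added to the
#'   reference (default 0.1; shared band components have unit variance).
#' @param source_noise_sd Standard deviation of broadband noise added to
#'   every source signal (default 0.05). A strictly band-limited signal has
#'   near-zero innovation variance, which makes spectral factorization and
#'   Granger measures ill-conditioned; a small broadband floor mimics the
#'   aperiodic background of real recordings and keeps them well-defined.
#' @param check Verify realized in-band source-reference coherence against
#'   `coherence_target` (warning beyond +/- 0.1). Default `TRUE`.
#' @return A `ts_recording` of sensors plus the reference channel, with
#'   attributes `sources` (noiseless source signal matrix), `spec`, and
#'   `realized_coherence`.
#' @export
generate_subject_recording <- function(spec, leadfield, duration_s = 180,
                                       fs = 300, sensor_snr = 1, seed,
                                       ref_label = "LFP",
                                       ref_noise_sd = 0.1,
                                       source_noise_sd = 0.05,
                                       check = TRUE) {
  n <- round(duration_s * fs)
  if (n < 4 * 2 * fs) stop("recording must cover at least 4 analysis windows")
  n_sens <- ncol(leadfield)
  set.seed(seed)
  maxlag <- max(c(1L, vapply(spec, function(s) s$coupling_lag, integer(1))))
  pad <- maxlag + fs
  nsrc <- length(spec)
  src <- matrix(0, n, max(1, nsrc))
  ref <- numeric(n)
  for (i in seq_len(nsrc)) {
    s <- spec[[i]]
    if (s$band$hi >= fs / 2) stop("source band above Nyquist")
    c0 <- s$coherence_target
    u <- .bandpass(stats::rnorm(n + pad), s$band, fs)
    if (s$direction == "bidirectional") {
      za <- .bandpass(stats::rnorm(n + pad), s$band, fs)
      zb <- .bandpass(stats::rnorm(n + pad), s$band, fs)
      src[, i] <- sqrt(c0 / 2) * (.lagged(za, 0, n) + .lagged(zb, s$coupling_lag, n)) +
        sqrt(1 - c0) * .lagged(u, 0, n)
      ref <- ref + (.lagged(za, s$coupling_lag, n) + .lagged(zb, 0, n)) / sqrt(2)
    } else {
      z <- .bandpass(stats::rnorm(n + pad), s$band, fs)
      lag_src <- if (s$direction == "ref_drives_source") s$coupling_lag else 0L
      lag_ref <- if (s$direction == "source_drives_ref") s$coupling_lag else 0L
      if (c0 > 0) {
        src[, i] <- sqrt(c0) * .lagged(z, lag_src, n) + sqrt(1 - c0) * .lagged(u, 0, n)
        ref <- ref + .lagged(z, lag_ref, n)
      } else {
        src[, i] <- .lagged(u, 0, n)
      }
    }
    src[, i] <- src[, i] + source_noise_sd * stats::rnorm(n)
  }
  ref <- ref + ref_noise_sd * stats::rnorm(n)
  ref <- .highpass1(ref, fs)
  if (nsrc > 0) {
    locs <- vapply(spec, function(s) s$location, integer(1))
    sensors <- src[, seq_len(nsrc), drop = FALSE] %*%
      leadfield[locs, , drop = FALSE]
    sig_var <- mean(apply(sensors, 2, stats::var))
    noise_sd <- if (is.finite(sensor_snr)) sqrt(sig_var / sensor_snr) else 0
    if (sig_var == 0) noise_sd <- if (is.finite(sensor_snr)) 1 else 0
  } else {
    sensors <- matrix(0, n, n_sens)
    noise_sd <- 1
  }
  sensors <- sensors + noise_sd * matrix(stats::rnorm(n * n_sens), n, n_sens)
  labels <- c(sprintf("S%03d", seq_len(n_sens)), ref_label)
  rec <- recording(cbind(sensors, ref), fs, labels)
  realized <- rep(NA_real_, nsrc)
  if (check && nsrc > 0) {
    for (i in seq_len(nsrc)) {
      if (spec[[i]]$coherence_target == 0) next
      cs <- compute_csd(recording(cbind(src = src[, i], ref = ref), fs),
                        window_s = 1)
      realized[i] <- band_average(coherence(cs, "src", "ref"), spec[[i]]$band)
      if (abs(realized[i] - spec[[i]]$coherence_target) > 0.1)
        warning(sprintf(
          "source %d realized coherence %.3f differs from target %.3f by > 0.1",
          i, realized[i], spec[[i]]$coherence_target))
    }
  }
  attr(rec, "sources") <- src[, seq_len(max(1, nsrc)), drop = FALSE]
  attr(rec, "spec") <- spec
  attr(rec, "realized_coherence") <- realized
  rec
}

#' Cohort specification for synthetic structure-function data
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_hemispheres_per_subject Observations per subject (default 2).
#' @param sfc_voxels m x 3 matrix of 1-based voxel indices where tract
#'   density is constructed to predict coherence across observations
#'   (positive slope), or `NULL` for a null cohort.
#' @param sfc_slope Density units added per unit coherence level at
#'   `sfc_voxels` (default 30).
#' @param nuisance_sd SD of per-subject and per-side additive density
#'   offsets (default 0).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_hemispheres_per_subject = 2,
                        sfc_voxels = NULL, sfc_slope = 30,
                        nuisance_sd = 0, seed = 1) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (!is.null(sfc_voxels)) sfc_voxels <- matrix(sfc_voxels, ncol = 3)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_hemispheres = as.integer(n_hemispheres_per_subject),
                 sfc_voxels = sfc_voxels, sfc_slope = sfc_slope,
                 nuisance_sd = nuisance_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of streamline sets with controlled voxel density
#'
#' Emits, for every observation (subject x hemisphere), a set of 1 mm
#' spaced polylines running from the seed sphere to target voxels such that
#' the expected count of streamlines terminating in voxel `v` equals
#' `target_map[v]`, plus - at the cohort's `sfc_voxels` - a linear function
#' (`sfc_slope`) of the observation's assigned coherence level. Counts are
#' integer (rounded Gaussian perturbation of the mean, SD `noise_sd`);
#' streamlines to distant voxels also traverse intermediate voxels, as real
#' fibres do.
#'
#' @param cohort A [cohort_spec()].
#' @param seed_center World mm centre of the seed sphere.
#' @param seed_radius Seed sphere radius in mm.
#' @param target_map `volume_image` of desired mean terminal density
#'   (nonnegative).
#' @param noise_sd SD of the count perturbation (density units; default 0).
#' @param coherence_levels Optional per-observation coherence levels in
#'   `[0, 1]`; defaults to uniform draws.
#' @return List with `streamlines` (list of `streamline_set`, one per
#'   observation), `table` (observation_id, subject, side), `levels`, and
#'   the voxel-index matrix `sfc_voxels`.
#' @export
generate_streamline_cohort <- function(cohort, seed_center, seed_radius,
                                       target_map, noise_sd = 0,
                                       coherence_levels = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(target_map, "volume_image"))
  if (any(target_map$data < 0, na.rm = TRUE))
    stop("target_map must be nonnegative")
  d <- dim(target_map$data)
  sc <- as.numeric(seed_center)
  scv <- world_to_voxel(target_map, matrix(sc, 1))
  if (any(scv < 0.5) || any(scv > d + 0.5))
    stop("seed sphere centre outside the volume")
  n_obs <- cohort$n_subjects * cohort$n_hemispheres
  set.seed(cohort$seed)
  if (is.null(coherence_levels)) coherence_levels <- stats::runif(n_obs)
  subj <- rep(seq_len(cohort$n_subjects), each = cohort$n_hemispheres)
  side <- rep_len(c("right", "left"), n_obs)
  subj_off <- stats::rnorm(cohort$n_subjects, 0, cohort$nuisance_sd)
  side_off <- stats::rnorm(2, 0, cohort$nuisance_sd)
  nz <- which(target_map$data > 0, arr.ind = TRUE)
  sfc_lin <- if (!is.null(cohort$sfc_voxels))
    .vox_linear(d, cohort$sfc_voxels) else integer(0)
  if (nrow(nz) == 0 && !length(sfc_lin)) {
    warning("target_map is all zero: emitting empty streamline sets")
  }
  all_lin <- union(.vox_linear(d, nz), sfc_lin)
  A <- target_map$affine
  out <- vector("list", n_obs)
  for (o in seq_len(n_obs)) {
    lines <- list()
    for (lin in all_lin) {
      v <- .lin_to_ijk(lin, d)
      m <- target_map$data[lin]
      if (lin %in% sfc_lin)
        m <- m + cohort$sfc_slope * coherence_levels[o]
      m <- m + subj_off[subj[o]] + side_off[match(side[o], c("right", "left"))]
      cnt <- if (noise_sd > 0)
        max(0L, as.integer(round(m + stats::rnorm(1, 0, noise_sd))))
      else max(0L, as.integer(round(m)))
      if (cnt == 0) next
      vc <- as.numeric(A %*% c(v - 1, 1))[1:3]      # voxel centre, world mm
      vs <- sqrt(colSums(A[1:3, 1:3]^2))
      for (s in seq_len(cnt)) {
        p0 <- sc + stats::runif(3, -0.3, 0.3) * seed_radius
        p1 <- vc + stats::runif(3, -0.45, 0.45) * vs
        lines[[length(lines) + 1L]] <- .polyline(p0, p1, step = 1)
      }
    }
    out[[o]] <- streamline_set(lines)
  }
  list(streamlines = out,
       table = data.frame(observation_id = sprintf("obs%02d", seq_len(n_obs)),
                          subject = sprintf("subj%02d", subj), side = side,
                          stringsAsFactors = FALSE),
       levels = coherence_levels,
       sfc_voxels = cohort$sfc_voxels)
}

.lin_to_ijk <- function(lin, d) {
  lin0 <- lin - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  c(i, j, k) + 1L
}

.polyline <- function(p0, p1, step = 1) {
  len <- sqrt(sum((p1 - p0)^2))
  nseg <- max(1L, ceiling(len / step))
  t <- seq(0, 1, length.out = nseg + 1)
  cbind(p0[1] + t * (p1[1] - p0[1]),
        p0[2] + t * (p1[2] - p0[2]),
        p0[3] + t * (p1[3] - p0[3]))
}

#' Generate a full synthetic structure-function cohort
#'
#' Convenience wrapper producing co-registered per-observation coherence
#' and tract-density images with a known planted coupling: each observation
#' gets a latent coherence level; at `sfc_voxels` the coherence image rises
#' linearly with the level (`coherence_amp`) and the streamline count rises
#' with slope `sfc_slope`, so across observations density predicts
#' coherence with positive slope exactly there. Everywhere else the two
#' modalities are independent.
#'
#' @param cohort A [cohort_spec()].
#' @param mask Binary `volume_image` (analysis mask and image geometry).
#' @param target_map `volume_image` of baseline mean density; defaults to a
#'   constant 20 inside the mask.
#' @param seed_center,seed_radius Seed sphere for the streamline generator;
#'   default centre at the mask centroid, radius 3 mm.
#' @param base_coherence,coherence_amp Baseline and per-level gain of the
#'   coherence image at `sfc_voxels` (defaults 0.2 and 0.3).
#' @param coherence_noise_sd SD of additive Gaussian noise on the coherence
#'   images (default 0.03).
#' @param density_noise_sd SD of the streamline count perturbation
#'   (default 4).
#' @param use_streamlines If `TRUE` (default) densities are obtained by
#'   generating and voxel-counting streamlines; if `FALSE` the integer
#'   counts are drawn directly per voxel (no pass-through fibres), which is
#'   faster for large calibration studies.
#' @return List with `coherence_imgs`, `density_imgs` (lists of
#'   `volume_image`), `table`, `levels`, `mask`, `sfc_voxels`.
#' @export
generate_sfc_cohort <- function(cohort, mask, target_map = NULL,
                                seed_center = NULL, seed_radius = 3,
                                base_coherence = 0.2, coherence_amp = 0.3,
                                coherence_noise_sd = 0.03,
                                density_noise_sd = 4,
                                use_streamlines = TRUE) {
  d <- dim(mask$data)
  inside <- mask$data > 0
  if (is.null(target_map)) {
    target_map <- mask
    target_map$data <- array(20 * as.numeric(inside), dim = d)
  }
  if (is.null(seed_center)) {
    ctr <- voxel_centers(mask)
    seed_center <- colMeans(ctr[as.logical(inside), , drop = FALSE])
  }
  n_obs <- cohort$n_subjects * cohort$n_hemispheres
  set.seed(cohort$seed)
  levels <- stats::runif(n_obs)
  sfc_lin <- if (!is.null(cohort$sfc_voxels))
    .vox_linear(d, cohort$sfc_voxels) else integer(0)

  if (use_streamlines) {
    cohort_sl <- cohort
    cohort_sl$seed <- cohort$seed + 100003L  # separate stream from `levels`
    sl <- generate_streamline_cohort(cohort_sl, seed_center, seed_radius,
                                     target_map, noise_sd = density_noise_sd,
                                     coherence_levels = levels)
    density_imgs <- lapply(sl$streamlines, density_image, template = mask)
    tab <- sl$table
  } else {
    subj <- rep(seq_len(cohort$n_subjects), each = cohort$n_hemispheres)
    side <- rep_len(c("right", "left"), n_obs)
    subj_off <- stats::rnorm(cohort$n_subjects, 0, cohort$nuisance_sd)
    side_off <- stats::rnorm(2, 0, cohort$nuisance_sd)
    density_imgs <- vector("list", n_obs)
    for (o in seq_len(n_obs)) {
      m <- target_map$data
      if (length(sfc_lin)) m[sfc_lin] <- m[sfc_lin] + cohort$sfc_slope * levels[o]
      m <- m + (subj_off[subj[o]] +
                  side_off[match(side[o], c("right", "left"))]) * inside
      cnt <- round(m + array(stats::rnorm(prod(d), 0, density_noise_sd), d))
      cnt[cnt < 0] <- 0
      cnt[!inside] <- 0
      density_imgs[[o]] <- volume_image(cnt, mask$affine)
    }
    tab <- data.frame(observation_id = sprintf("obs%02d", seq_len(n_obs)),
                      subject = sprintf("subj%02d", subj), side = side,
                      stringsAsFactors = FALSE)
  }
  set.seed(cohort$seed + 200003L)
  coherence_imgs <- vector("list", n_obs)
  for (o in seq_len(n_obs)) {
    cimg <- array(NA_real_, d)
    cimg[inside] <- base_coherence +
      stats::rnorm(sum(inside), 0, coherence_noise_sd)
    if (length(sfc_lin))
      cimg[sfc_lin] <- cimg[sfc_lin] + coherence_amp * levels[o]
    coherence_imgs[[o]] <- volume_image(cimg, mask$affine)
  }
  list(coherence_imgs = coherence_imgs, density_imgs = density_imgs,
       table = tab, levels = levels, mask = mask,
       sfc_voxels = cohort$sfc_voxels)
}
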