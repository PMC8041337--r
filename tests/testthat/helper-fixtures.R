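# Shared fixtures and independent oracles used across the test files.

# classic bivariate VAR(2) with unidirectional coupling channel 1 -> 2:
# oscillatory poles near 40 Hz at fs = 200
var_fixture <- function() {
  A <- array(0, c(2, 2, 2))
  A[1, , ] <- matrix(c(0.55, 0.25, 0, 0.55), 2, 2)  # A1[2,1] = 0.25
  A[2, , ] <- matrix(c(-0.8, 0, 0, -0.8), 2, 2)
  list(coeffs = A, noise_cov = diag(2), fs = 200,
       band = frequency_band("coupled", 30, 50))
}

small_mask <- function(n = 10, vs = 2) {
  volume_image(array(1, c(n, n, n)),
               make_affine(rep(vs, 3), rep(-(n - 1) * vs / 2, 3)))
}

# analytic autocovariance sequence of a VAR via the companion-form
# discrete Lyapunov equation (vec trick); Gamma[[h+1]] = E[X_{t+h} X_t']
var_autocov_oracle <- function(coeffs, noise_cov, max_lag) {
  p <- dim(coeffs)[1]; k <- dim(coeffs)[2]
  Fm <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) Fm[1:k, (l - 1) * k + 1:k] <- coeffs[l, , ]
  if (p > 1) Fm[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  Q <- matrix(0, k * p, k * p)
  Q[1:k, 1:k] <- noise_cov
  G0 <- matrix(solve(diag((k * p)^2) - kronecker(Fm, Fm), as.vector(Q)),
               k * p, k * p)
  out <- vector("list", max_lag + 1)
  Gh <- G0
  out[[1]] <- G0[1:k, 1:k]
  for (h in seq_len(max_lag)) {
    Gh <- Fm %*% Gh
    out[[h + 1]] <- Gh[1:k, 1:k]
  }
  out
}

# brute-force voxel-visit oracle: set of voxels within `step`-resampled
# points of a polyline, by exhaustive nearest-voxel assignment
voxel_visits_oracle <- function(m, template, step = 0.05) {
  fine <- m
  if (nrow(m) > 1) {
    pieces <- list()
    for (i in seq_len(nrow(m) - 1)) {
      len <- sqrt(sum((m[i + 1, ] - m[i, ])^2))
      t <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
      pieces[[i]] <- cbind(m[i, 1] + t * (m[i + 1, 1] - m[i, 1]),
                           m[i, 2] + t * (m[i + 1, 2] - m[i, 2]),
                           m[i, 3] + t * (m[i + 1, 3] - m[i, 3]))
    }
    fine <- do.call(rbind, pieces)
  }
  ijk <- round(world_to_voxel(template, fine))
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(template$data)[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dim(template$data)[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dim(template$data)[3]
  as.integer(sort(unique((ijk[ok, 3] - 1) * prod(dim(template$data)[1:2]) +
                            (ijk[ok, 2] - 1) * dim(template$data)[1] +
                            ijk[ok, 1])))
}

# brute-force min distance from a point to a polyline's segments
point_polyline_dist_oracle <- function(pt, m) {
  if (nrow(m) == 1) return(sqrt(sum((m[1, ] - pt)^2)))
  dmin <- Inf
  for (i in seq_len(nrow(m) - 1)) {
    a <- m[i, ]; b <- m[i + 1, ]
    ab <- b - a
    t <- max(0, min(1, sum((pt - a) * ab) / sum(ab^2)))
    dmin <- min(dmin, sqrt(sum((a + t * ab - pt)^2)))
  }
  dmin
}

# two-channel recording with a directed band-limited coupling, built from
# the synthetic generator's source + reference pair
directed_pair <- function(seed, band = canonical_bands()$low_beta,
                          coherence = 0.6, lag = 6L,
                          direction = "source_drives_ref",
                          duration_s = 60, fs = 300) {
  L <- make_toy_leadfield(rbind(c(10, 10, 5), c(-10, 5, 0)),
                          toy_sensor_array(12, 80))
  sp <- list(source_spec(1, band, coherence, direction, lag))
  rec <- generate_subject_recording(sp, L, duration_s = duration_s, fs = fs,
                                    sensor_snr = 1, seed = seed,
                                    check = FALSE)
  recording(cbind(SRC = attr(rec, "sources")[, 1],
                  LFP = rec$data[, "LFP"]), fs)
}

white_pair <- function(seed, duration_s = 30, fs = 300) {
  set.seed(seed)
  recording(matrix(stats::rnorm(2 * duration_s * fs), ncol = 2,
                   dimnames = list(NULL, c("SRC", "LFP"))), fs)
}
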