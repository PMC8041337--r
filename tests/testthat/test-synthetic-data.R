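test_that("VAR simulator reproduces known moments and is deterministic", {
  # univariate, zero coefficients: white noise with unit variance
  r <- simulate_var_sources(array(0, c(1, 1, 1)), matrix(1), 20000, seed = 1)
  se <- sqrt(2 / 20000)                      # SE of sample variance
  expect_lt(abs(var(r$data[, 1]) - 1), 3 * se)
  r2 <- simulate_var_sources(array(0, c(1, 1, 1)), matrix(1), 20000, seed = 1)
  expect_identical(r$data, r2$data)
})

test_that("VAR cross-correlation peaks at the lag the Lyapunov oracle predicts", {
  A <- array(0, c(2, 2, 2))
  A[1, , ] <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)   # A1[2,1] = 0.5, 1 drives 2
  A[2, , ] <- matrix(c(-0.3, 0, 0, -0.3), 2, 2)
  G <- var_autocov_oracle(A, diag(2), 10)
  # E[x2_{t+h} x1_t] across h = 0..10: oracle peak lag
  cc_oracle <- vapply(0:10, function(h) G[[h + 1]][2, 1], numeric(1))
  h_star <- which.max(cc_oracle) - 1
  expect_gt(h_star, 0)                       # channel 1 leads
  r <- simulate_var_sources(A, diag(2), 50000, seed = 3)
  emp <- stats::ccf(r$data[, 2], r$data[, 1], lag.max = 10, plot = FALSE)
  emp_pos <- emp$acf[emp$lag >= 0]
  expect_equal(which.max(emp_pos) - 1, h_star)
})

test_that("VAR validation rejects unstable and non-SPD inputs", {
  A <- array(0, c(1, 2, 2)); A[1, , ] <- diag(c(1.05, 0.2))
  expect_error(simulate_var_sources(A, diag(2), 100, seed = 1), "unstable")
  A[1, , ] <- diag(c(0.5, 0.5))
  expect_error(simulate_var_sources(A, matrix(c(1, 2, 2, 1), 2), 100,
                                    seed = 1), "positive definite")
})

test_that("toy leadfield rows are unit norm with nearest-sensor dominance", {
  sens <- toy_sensor_array(10, 50)
  grid <- rbind(c(0, 0, 10), c(5, 5, 0))
  L <- make_toy_leadfield(grid, sens)
  expect_lt(max(abs(rowSums(L^2) - 1)), 1e-12)
  cossim <- sum(L[1, ] * L[2, ])
  expect_lt(cossim, 1 - 1e-6)                # rows differ
  for (g in 1:2) {
    d2 <- colSums((t(sens) - grid[g, ])^2)
    expect_equal(which.max(L[g, ]), which.min(d2))  # inverse-distance gain
  }
  expect_error(make_toy_leadfield(sens[1, , drop = FALSE], sens),
               "coincides")
  expect_error(make_toy_leadfield(grid, sens[1:4, ]), "8 sensors")
})

test_that("generated recordings hit their coherence targets", {
  band <- canonical_bands()$low_beta
  L <- make_toy_leadfield(rbind(c(10, 10, 5), c(-10, 0, 0)),
                          toy_sensor_array(12, 80))
  sp <- list(source_spec(1, band, 1, "source_drives_ref", 5L))
  rec <- generate_subject_recording(sp, L, duration_s = 180, fs = 300,
                                    sensor_snr = Inf, seed = 21,
                                    source_noise_sd = 0, check = FALSE)
  best <- which.max(L[1, ])
  co <- coherence(compute_csd(rec, window_s = 1),
                  sprintf("S%03d", best), "LFP")
  expect_gt(band_average(co, band), 0.9)
  # empty spec: sensors are pure noise, no coherence with the reference
  rec0 <- generate_subject_recording(list(), L, duration_s = 180, fs = 300,
                                     sensor_snr = 1, seed = 22)
  co0 <- coherence(compute_csd(rec0, window_s = 1), "S001", "LFP")
  expect_lt(band_average(co0, frequency_band("wide", 2, 30)), 0.05)
  # a band above Nyquist is rejected
  expect_error(generate_subject_recording(
    list(source_spec(1, frequency_band("hf", 120, 160), 0.5,
                     "source_drives_ref", 2L)),
    L, duration_s = 20, fs = 300, sensor_snr = 1, seed = 1), "Nyquist")
})

test_that("directed coupling yields the specified Granger asymmetry", {
  # the raw reverse-direction estimate carries a weak-asymmetry bias from
  # the shared band-limited innovations, so the recovery criterion is the
  # asymmetry sign and, more stringently, the time-reversal differences
  band <- canonical_bands()$low_beta
  for (s in 31:33) {
    g <- granger_bivariate(directed_pair(s, band, direction =
                                           "source_drives_ref"),
                           c("SRC", "LFP"), bands = list(b = band))
    expect_gt(g$original$band_means["xy", "b"],
              g$original$band_means["yx", "b"])
    expect_gt(g$delta["xy", "b"], 0)
    expect_lt(g$delta["yx", "b"], 0)
  }
  g2 <- granger_bivariate(directed_pair(36, band, direction =
                                          "ref_drives_source"),
                          c("SRC", "LFP"), bands = list(b = band))
  expect_gt(g2$original$band_means["yx", "b"],
            g2$original$band_means["xy", "b"])
  expect_gt(g2$delta["yx", "b"], 0)
  expect_lt(g2$delta["xy", "b"], 0)
})

test_that("source_spec and cohort_spec enforce their invariants", {
  b <- canonical_bands()$low_beta
  expect_error(source_spec(1, b, 1.2, "none"), "coherence_target")
  expect_error(source_spec(1, b, 0.5, "source_drives_ref", 0L), "coupling_lag")
  expect_error(cohort_spec(2), "3 subjects")
})

test_that("streamline cohort realizes its target density exactly when noiseless", {
  tpl <- small_mask(10, 2)
  target <- tpl
  target$data[] <- 0
  target$data[6, 6, 6] <- 5
  vc <- as.numeric(tpl$affine %*% c(5, 5, 5, 1))[1:3]   # centre of (6,6,6)
  ch <- cohort_spec(3, 2, seed = 9)
  sl <- generate_streamline_cohort(ch, seed_center = vc, seed_radius = 0.8,
                                   target_map = target, noise_sd = 0)
  for (o in seq_along(sl$streamlines)) {
    di <- density_image(sl$streamlines[[o]], tpl)
    expect_equal(di$data[6, 6, 6], 5)
    expect_equal(sum(di$data), 5)            # nothing outside that voxel
  }
  # every streamline passes within the seed radius (brute-force distance)
  for (m in sl$streamlines[[1]]$streamlines)
    expect_lte(point_polyline_dist_oracle(vc, m), 0.8)
})

test_that("doubling the target map doubles the mean recovered density", {
  tpl <- small_mask(10, 2)
  target <- tpl; target$data[] <- 0
  target$data[6, 6, 6] <- 6; target$data[3, 7, 5] <- 4
  vc <- as.numeric(tpl$affine %*% c(5, 5, 5, 1))[1:3]
  mean_density <- function(mult, seed) {
    t2 <- target; t2$data <- t2$data * mult
    ch <- cohort_spec(10, 2, seed = seed)
    sl <- generate_streamline_cohort(ch, vc, 2, t2, noise_sd = 2)
    mean(vapply(sl$streamlines, function(s)
      density_image(s, tpl)$data[6, 6, 6], numeric(1)))
  }
  m1 <- mean_density(1, 41)
  m2 <- mean_density(2, 42)
  expect_equal(m2 / m1, 2, tolerance = 0.2)
})

test_that("an all-zero target map warns and yields empty sets", {
  tpl <- small_mask(6, 2)
  target <- tpl; target$data[] <- 0
  ch <- cohort_spec(3, 1, seed = 2)
  expect_warning(sl <- generate_streamline_cohort(ch, c(0, 0, 0), 2, target),
                 "all zero")
  expect_true(all(vapply(sl$streamlines, n_streamlines, integer(1)) == 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  tpl <- small_mask(8, 2)
  target <- tpl; target$data[] <- 0; target$data[4, 4, 4] <- 3
  ch <- cohort_spec(3, 2, seed = 77)
  s1 <- generate_streamline_cohort(ch, c(0, 0, 0), 2, target, noise_sd = 1)
  s2 <- generate_streamline_cohort(ch, c(0, 0, 0), 2, target, noise_sd = 1)
  expect_identical(s1$streamlines, s2$streamlines)
  expect_identical(s1$levels, s2$levels)
  L <- make_toy_leadfield(rbind(c(5, 5, 5), c(-5, 0, 0)),
                          toy_sensor_array(12, 60))
  sp <- list(source_spec(1, canonical_bands()$delta_theta, 0.5,
                         "source_drives_ref", 4L))
  r1 <- generate_subject_recording(sp, L, 20, 300, 1, seed = 5, check = FALSE)
  r2 <- generate_subject_recording(sp, L, 20, 300, 1, seed = 5, check = FALSE)
  expect_identical(r1$data, r2$data)
})
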