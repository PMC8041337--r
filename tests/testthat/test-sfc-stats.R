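make_image_list <- function(arrs, affine) {
  lapply(arrs, function(a) volume_image(a, affine))
}

test_that("a perfect linear relationship is flagged as an exact fit", {
  mask <- small_mask(4, 2)
  dens <- lapply(1:10, function(i) {
    a <- array(0, c(4, 4, 4)); a[] <- i + seq_len(64) %% 3
    volume_image(a, mask$affine)
  })
  coh <- lapply(dens, function(d)
    volume_image(0.1 + 0.02 * d$data, mask$affine))
  res <- voxelwise_sfc_glm(coh, dens, mask = mask)
  expect_true(all(res$exact_fit[mask$data > 0]))
  expect_true(all(res$F_image$data == .Machine$double.xmax, na.rm = TRUE))
  expect_equal(res$beta_image$data[1, 1, 1], 0.02, tolerance = 1e-10)
})

test_that("null voxel F statistics follow the F(1, n-2) distribution", {
  # independent Gaussian coherence vs integer density: conditional on the
  # regressors the slope F is exactly F(1, 8) at n = 10
  mask <- volume_image(array(1, c(13, 13, 13)),
                       make_affine(c(2, 2, 2), rep(-12, 3)))
  ch <- cohort_spec(5, 2, sfc_voxels = NULL, seed = 101)
  co <- generate_sfc_cohort(ch, mask, use_streamlines = FALSE)
  res <- voxelwise_sfc_glm(co$coherence_imgs, co$density_imgs, mask = mask)
  expect_equal(res$df, c(1, 8))
  Fv <- res$F_image$data[res$mask$data > 0]
  Fv <- Fv[is.finite(Fv)]
  expect_gt(length(Fv), 2000)
  ks <- suppressWarnings(stats::ks.test(Fv, stats::pf, 1, 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted slope signs are recovered at the coupled voxels", {
  mask <- small_mask(10, 2)
  blob <- as.matrix(expand.grid(4:5, 4:5, 4:5))
  ok <- 0
  for (seed in 1:5) {
    ch <- cohort_spec(5, 2, sfc_voxels = blob, sfc_slope = 30, seed = seed)
    co <- generate_sfc_cohort(ch, mask, use_streamlines = FALSE)
    res <- voxelwise_sfc_glm(co$coherence_imgs, co$density_imgs, mask = mask)
    if (all(res$beta_image$data[blob] > 0)) ok <- ok + 1
  }
  expect_gte(ok, 5 * 0.95 - 1)   # >= 4 of 5 seeds with all-positive slopes
})

test_that("the GLM F is invariant to affine rescaling of density", {
  mask <- small_mask(6, 2)
  set.seed(40)
  dens <- make_image_list(lapply(1:8, function(i)
    array(rpois(216, 20), c(6, 6, 6))), mask$affine)
  coh <- make_image_list(lapply(1:8, function(i)
    array(runif(216, 0.1, 0.4), c(6, 6, 6))), mask$affine)
  r1 <- voxelwise_sfc_glm(coh, dens, mask = mask)
  dens2 <- lapply(dens, function(d)
    volume_image(3.2 * d$data - 41, d$affine))
  r2 <- voxelwise_sfc_glm(coh, dens2, mask = mask)
  expect_equal(r1$F_image$data, r2$F_image$data, tolerance = 1e-8)
  expect_equal(r2$beta_image$data, r1$beta_image$data / 3.2,
               tolerance = 1e-8)
})

test_that("with a voxel-constant design the GLM matches a direct lm fit", {
  mask <- volume_image(array(1, c(5, 5, 4)),
                       make_affine(c(2, 2, 2), c(0, 0, 0)))
  n <- 9
  set.seed(41)
  x <- rnorm(n, 10, 3)                        # one density value per obs
  dens <- make_image_list(lapply(x, function(v)
    array(v, c(5, 5, 4))), mask$affine)
  coh <- make_image_list(lapply(1:n, function(i)
    array(rnorm(100, 0.3, 0.05), c(5, 5, 4))), mask$affine)
  res <- voxelwise_sfc_glm(coh, dens, mask = mask)
  Y <- vapply(coh, function(im) as.vector(im$data), numeric(100))
  for (v in c(1, 37, 100)) {
    fit <- summary(stats::lm(Y[v, ] ~ x))
    expect_equal(res$F_image$data[v], unname(fit$fstatistic[1]),
                 tolerance = 1e-8)
  }
})

test_that("zero-variance density voxels are undefined and excluded from clusters", {
  mask <- small_mask(6, 2)
  set.seed(42)
  dens <- make_image_list(lapply(1:8, function(i) {
    a <- array(rpois(216, 20), c(6, 6, 6))
    a[3, , ] <- 5                     # constant wall across observations
    a
  }), mask$affine)
  coh <- make_image_list(lapply(1:8, function(i)
    array(rnorm(216, 0.3, 0.05), c(6, 6, 6))), mask$affine)
  res <- voxelwise_sfc_glm(coh, dens, mask = mask)
  expect_true(all(is.na(res$F_image$data[3, , ])))
  cl <- cluster_permutation(res, forming_p = 0.5, n_perm = 100, seed = 1)
  # no cluster may contain an undefined voxel
  lab <- cl$label_image$data
  expect_true(all(lab[3, , ] == 0))
})

test_that("geometry mismatches and constant designs raise errors", {
  mask <- small_mask(4, 2)
  set.seed(43)
  dens <- make_image_list(lapply(1:5, function(i)
    array(rpois(64, 10), c(4, 4, 4))), mask$affine)
  coh <- make_image_list(lapply(1:5, function(i)
    array(runif(64), c(4, 4, 4))), mask$affine)
  bad <- coh
  bad[[2]] <- volume_image(array(0.2, c(5, 5, 5)), mask$affine)
  expect_error(voxelwise_sfc_glm(bad, dens, mask = mask), "shapes differ")
  bad2 <- coh
  bad2[[2]] <- volume_image(bad2[[2]]$data, make_affine(c(3, 3, 3),
                                                        c(0, 0, 0)))
  expect_error(voxelwise_sfc_glm(bad2, dens, mask = mask), "affines differ")
  const <- make_image_list(lapply(1:5, function(i)
    array(7, c(4, 4, 4))), mask$affine)
  expect_error(voxelwise_sfc_glm(coh, const, mask = mask), "constant")
  expect_error(voxelwise_sfc_glm(coh[1:3], dens[1:3], mask = mask),
               "at least 4")
})

test_that("cluster permutation respects its estimator floor and is reproducible", {
  mask <- small_mask(8, 2)
  blob <- as.matrix(expand.grid(4:5, 4:5, 4:5))
  ch <- cohort_spec(5, 2, sfc_voxels = blob, sfc_slope = 30, seed = 7)
  co <- generate_sfc_cohort(ch, mask, use_streamlines = FALSE)
  res <- voxelwise_sfc_glm(co$coherence_imgs, co$density_imgs, mask = mask)
  cl1 <- cluster_permutation(res, forming_p = 0.01, n_perm = 200, seed = 5)
  cl2 <- cluster_permutation(res, forming_p = 0.01, n_perm = 200, seed = 5)
  expect_identical(cl1$table, cl2$table)
  expect_true(all(cl1$table$p_fwe >= 1 / 201))
  # FWE p is nonincreasing in cluster size
  tab <- cl1$table[order(cl1$table$size), ]
  expect_true(all(diff(tab$p_fwe) <= 1e-12))
  expect_error(cluster_permutation(res, n_perm = 50), "n_perm")
  expect_error(cluster_permutation(res, forming_p = 1.2, n_perm = 100),
               "forming_p")
})

test_that("26-connectivity labeling merges diagonal neighbours", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE       # touch only diagonally
  m[4, 4, 4] <- TRUE                           # isolated
  lab <- label_components_26(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[4, 4, 4] != lab[1, 1, 1])
  expect_equal(max(label_components_26(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("f_tail_p maps F statistics to upper-tail probabilities", {
  expect_equal(f_tail_p(0, 1, 8), 1)
  expect_error(f_tail_p(-1, 1, 8), "nonnegative")
  expect_error(f_tail_p(1, 0, 8), "degrees of freedom")
  expect_equal(f_tail_p(2, 3, 10),
               1 - stats::pf(2, 3, 10))
})
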