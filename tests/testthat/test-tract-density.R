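test_that("a straight 10 mm streamline marks exactly five 2 mm voxels", {
  tpl <- volume_image(array(0, c(10, 10, 10)), make_affine(c(2, 2, 2),
                                                           c(0, 0, 0)))
  # voxel centres at x = 0, 2, ..., faces at odd x; start just inside the
  # face at x = 1 and run 10 mm along x
  m <- cbind(seq(1.01, 10.99, length.out = 11), 4, 4)
  s <- streamline_set(list(m))
  di <- density_image(s, tpl)
  expect_equal(sum(di$data > 0), 5)
  expect_true(all(di$data[di$data > 0] == 1))
  expect_identical(sort(which(di$data > 0)), voxel_visits_oracle(m, tpl))
  # the same streamline duplicated counts twice
  d2 <- density_image(streamline_set(list(m, m)), tpl)
  expect_true(all(d2$data[d2$data > 0] == 2))
})

test_that("a streamline looping twice through a voxel counts once", {
  tpl <- volume_image(array(0, c(8, 8, 8)), make_affine(c(2, 2, 2),
                                                        c(0, 0, 0)))
  # out-and-back path revisiting the same voxels
  loop <- rbind(c(4, 4, 4), c(9, 4, 4), c(4, 4, 4), c(9, 4, 4))
  di <- density_image(streamline_set(list(loop)), tpl)
  expect_true(all(di$data[di$data > 0] == 1))
  expect_identical(sort(which(di$data > 0)), voxel_visits_oracle(loop, tpl))
})

test_that("density counting is order-invariant and additive", {
  tpl <- small_mask(8, 2)
  set.seed(12)
  lines <- lapply(1:6, function(i) {
    p0 <- runif(3, -6, 6); p1 <- runif(3, -6, 6)
    rbind(p0, (p0 + p1) / 2, p1)
  })
  s <- streamline_set(lines)
  d_all <- density_image(s, tpl)
  d_rev <- density_image(streamline_set(rev(lines)), tpl)
  expect_identical(d_all$data, d_rev$data)
  d_a <- density_image(streamline_set(lines[1:3]), tpl)
  d_b <- density_image(streamline_set(lines[4:6]), tpl)
  expect_identical(d_all$data, d_a$data + d_b$data)
})

test_that("flipping streamlines commutes with counting on the symmetric grid", {
  tpl <- symmetric_template(13, 2)
  set.seed(13)
  lines <- lapply(1:5, function(i) {
    p0 <- runif(3, -10, 10); p1 <- runif(3, -10, 10)
    rbind(p0, p1)
  })
  s <- streamline_set(lines)
  flipped <- streamline_set(lapply(lines, function(m)
    m %*% diag(c(-1, 1, 1))))
  expect_identical(density_image(flipped, tpl)$data,
                   flip_midsagittal(density_image(s, tpl))$data)
})

test_that("seed-sphere and structure-mask filtering follow their contracts", {
  msk <- small_mask(10, 2)
  msk$data[] <- 0
  msk$data[6:8, 5:6, 5:6] <- 1                   # structure of interest
  roi <- seed_roi(c(0, 0, 0), 3, msk)
  through <- rbind(c(-8, 0, 0), c(0, 0, 0), c(3, 1, 1))   # sphere + mask
  sphere_only <- rbind(c(-2, -2, -2), c(-2, 2, -2))       # misses the mask
  miss <- rbind(c(-8, 8, 8), c(8, 8, 8))                  # misses the sphere
  s <- streamline_set(list(through, sphere_only, miss))
  kept <- filter_streamlines(s, roi)
  expect_equal(n_streamlines(kept), 1)
  expect_identical(kept$streamlines[[1]], s$streamlines[[1]])
  # a streamline whose closest point is radius + 0.1 away is dropped
  graze <- rbind(c(-6, 3.1, 0), c(0, 3.1, 0), c(3, 3.1, 1.1))
  expect_gt(point_polyline_dist_oracle(roi$center, graze), roi$radius)
  kept2 <- filter_streamlines(streamline_set(list(graze)), roi)
  expect_equal(n_streamlines(kept2), 0)
  expect_warning(filter_streamlines(streamline_set(list()), roi), "empty")
  expect_error(seed_roi(c(0, 0, 0), 3,
                        volume_image(array(2, c(2, 2, 2)), diag(4))),
               "binary")
})

test_that("the density ANOVA recovers a planted location effect", {
  mask <- small_mask(10, 2)
  tab <- expand.grid(loc = c("NBM", "GP"), side = c("right", "left"),
                     subject = sprintf("s%d", 1:5))
  tab$disease <- ifelse(match(tab$subject, unique(tab$subject)) <= 3,
                        "PDD", "DLB")
  blob <- as.matrix(expand.grid(4:5, 4:5, 4:5))
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    imgs <- lapply(seq_len(nrow(tab)), function(i) {
      d <- array(round(pmax(0, 20 + rnorm(1000, 0, 4))), c(10, 10, 10))
      if (tab$loc[i] == "NBM") d[blob] <- d[blob] + 12
      volume_image(d, mask$affine)
    })
    res <- density_anova(imgs, tab$loc, tab$disease, tab$subject, tab$side,
                         effect = "location", mask = mask, n_perm = 200,
                         seed = seed)
    sig <- res$clusters$table[res$clusters$table$p_fwe < 0.01, ]
    blob_lin <- (blob[, 3] - 1) * 100 + (blob[, 2] - 1) * 10 + blob[, 1]
    if (nrow(sig) >= 1 &&
        all(vapply(sig$label, function(l)
          any(which(res$clusters$label_image$data == l) %in% blob_lin),
          logical(1))))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("swapping location labels negates the contrast T-map exactly", {
  mask <- small_mask(6, 2)
  tab <- expand.grid(loc = c("NBM", "GP"), side = c("right", "left"),
                     subject = sprintf("s%d", 1:4))
  tab$disease <- ifelse(match(tab$subject, unique(tab$subject)) <= 2,
                        "PDD", "DLB")
  set.seed(30)
  imgs <- lapply(seq_len(nrow(tab)), function(i)
    volume_image(array(round(20 + rnorm(216, 0, 4)), c(6, 6, 6)),
                 mask$affine))
  loc_sw <- ifelse(tab$loc == "NBM", "GP", "NBM")
  r1 <- density_anova(imgs, tab$loc, tab$disease, tab$subject, tab$side,
                      effect = "location", mask = mask, n_perm = 100,
                      seed = 1)
  r2 <- density_anova(imgs, factor(loc_sw, levels = c("NBM", "GP")),
                      tab$disease, tab$subject, tab$side,
                      effect = "location", mask = mask, n_perm = 100,
                      seed = 1)
  expect_equal(r1$T_image$data, -r2$T_image$data, tolerance = 1e-10)
  expect_equal(r1$F_image$data, r2$F_image$data, tolerance = 1e-10)
})

test_that("an aliased design is rejected with the offending columns named", {
  mask <- small_mask(6, 2)
  # side perfectly confounded with location
  tab <- expand.grid(loc = c("NBM", "GP"), subject = sprintf("s%d", 1:4))
  tab$side <- ifelse(tab$loc == "NBM", "right", "left")
  tab$disease <- ifelse(match(tab$subject, unique(tab$subject)) <= 2,
                        "PDD", "DLB")
  set.seed(31)
  imgs <- lapply(seq_len(nrow(tab)), function(i)
    volume_image(array(rnorm(216, 20, 3), c(6, 6, 6)), mask$affine))
  expect_error(density_anova(imgs, tab$loc, tab$disease, tab$subject,
                             tab$side, effect = "location", mask = mask,
                             n_perm = 100, seed = 1),
               "aliased")
})
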