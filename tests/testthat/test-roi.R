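# Geometry oracles: voxelized spheres/cylinders/expansions must equal
# exhaustive center-inclusion scans, on isotropic and anisotropic grids.

test_that("sphere voxelization equals the exhaustive center-inclusion scan", {
  for (sp in list(c(1, 1, 1), c(0.7, 0.7, 2.5))) {
    fl <- full_lung_volume(c(31L, 31L, 15L), sp)
    ctr_idx <- (c(31, 31, 15) - 1) / 2
    ctr <- voxel_to_world(fl$vol, ctr_idx)
    a <- recist_annotation(ctr - c(5, 0, 0), ctr + c(5, 0, 0), round(ctr_idx[3]))
    m <- build_sphere(a, 20, fl$vol, fl$lung)
    # oracle: scan every voxel center
    idx <- which(array(TRUE, dim(fl$vol$data)), arr.ind = TRUE)
    w <- voxel_to_world(fl$vol, idx - 1)
    inside <- rowSums(sweep(w, 2, ctr)^2) <= 100 + 1e-9
    expect_identical(as.vector(m$mask), as.vector(inside))
    expect_true(all(fl$lung$mask[m$mask]))
  }
})

test_that("sub-voxel spheres collapse to the midpoint voxel", {
  fl <- full_lung_volume(c(11L, 11L, 5L), c(1, 1, 1))
  ctr <- c(5, 5, 2)
  a <- recist_annotation(ctr - c(0.2, 0, 0), ctr + c(0.2, 0, 0), 2)
  m <- build_sphere(a, 0.4, fl$vol, fl$lung)
  expect_identical(sum(m$mask), 1L)
  expect_true(m$mask[6, 6, 3])
})

test_that("cylinder voxelization equals the exhaustive scan and respects its bounds", {
  fl <- full_lung_volume(c(31L, 31L, 21L), c(1, 1, 1))
  p1 <- c(10, 15, 10); p2 <- c(20, 15, 10)
  a <- recist_annotation(p1, p2, 10)
  m <- build_cylinder(a, 10, fl$vol, fl$lung)
  idx <- which(array(TRUE, dim(fl$vol$data)), arr.ind = TRUE)
  w <- voxel_to_world(fl$vol, idx - 1)
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  rel <- sweep(w, 2, p1)
  t <- as.numeric(rel %*% u)
  perp2 <- rowSums(rel^2) - t^2
  inside <- t >= -1e-9 & t <= 10 + 1e-9 & perp2 <= 100 + 1e-9
  expect_identical(as.vector(m$mask), as.vector(inside))
  # the axis midpoint voxel is inside; a point 10.5 mm off-axis is not
  expect_true(m$mask[16, 16, 11])
  expect_false(m$mask[16, 16 + 11, 11])
  # anisotropic grid
  fl2 <- full_lung_volume(c(41L, 41L, 9L), c(0.74, 0.74, 5))
  p1 <- voxel_to_world(fl2$vol, c(10, 20, 4)); p2 <- voxel_to_world(fl2$vol, c(30, 20, 4))
  a2 <- recist_annotation(p1, p2, 4)
  m2 <- build_cylinder(a2, 6, fl2$vol, fl2$lung)
  w2 <- voxel_to_world(fl2$vol, which(array(TRUE, dim(fl2$vol$data)), arr.ind = TRUE) - 1)
  u2 <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  rel2 <- sweep(w2, 2, p1)
  t2 <- as.numeric(rel2 %*% u2)
  perp22 <- rowSums(rel2^2) - t2^2
  L2 <- sqrt(sum((p2 - p1)^2))
  inside2 <- t2 >= -1e-9 & t2 <= L2 + 1e-9 & perp22 <= 36 + 1e-9
  expect_identical(as.vector(m2$mask), as.vector(inside2))
})

test_that("the lung-slice ROI is the lung restricted to the RECIST slice", {
  fl <- full_lung_volume(c(15L, 15L, 7L), c(1, 1, 2.5))
  # carve a non-trivial lung
  fl$lung$mask[1:3, , ] <- FALSE
  a <- recist_annotation(c(5, 5, 5), c(9, 5, 5), 2)
  m <- build_lung_slice(a, fl$vol, fl$lung)
  expect_true(m$two_d)
  k <- round(world_to_voxel(fl$vol, a$p1)[3]) + 1
  expect_identical(m$mask[, , k], fl$lung$mask[, , k])
  expect_true(all(!m$mask[, , -k]))
})

test_that("GGO expansion equals the exhaustive anisotropic distance scan", {
  dimg <- c(25L, 25L, 9L)
  sp <- c(1, 1, 2.5)
  fl <- full_lung_volume(dimg, sp)
  solid_arr <- array(FALSE, dimg)
  solid_arr[12:14, 12:13, 4:5] <- TRUE
  solid <- roi_mask(solid_arr, fl$vol, "solid")
  g <- expand_ggo(solid, 6, fl$lung)
  # oracle: min distance from every voxel center to every solid center
  idx_all <- which(array(TRUE, dimg), arr.ind = TRUE)
  w_all <- voxel_to_world(fl$vol, idx_all - 1)
  w_sol <- voxel_to_world(fl$vol, which(solid_arr, arr.ind = TRUE) - 1)
  mind <- apply(w_all, 1, function(p) {
    sqrt(min(colSums((t(w_sol) - p)^2)))
  })
  oracle <- mind <= 6 + 1e-9 & !as.vector(solid_arr)
  expect_identical(as.vector(g$mask), oracle)
  expect_false(any(g$mask & solid_arr))

  # single-voxel solid at 1 mm isotropic with width exactly 1: 6-face shell
  fl3 <- full_lung_volume(c(9L, 9L, 9L), c(1, 1, 1))
  s3 <- array(FALSE, c(9L, 9L, 9L)); s3[5, 5, 5] <- TRUE
  g3 <- expand_ggo(roi_mask(s3, fl3$vol, "solid"), 1, fl3$lung)
  expect_identical(sum(g3$mask), 6L)
  # width below the spacing leaves no voxel center in range
  expect_error(expand_ggo(roi_mask(s3, fl3$vol, "solid"), 0.5, fl3$lung), "empty")
})

test_that("the RECIST-sphere volume is monotone in the line length", {
  fl <- full_lung_volume(c(41L, 41L, 17L), c(1, 1, 2))
  ctr <- voxel_to_world(fl$vol, c(20, 20, 8))
  vols <- vapply(c(6, 10, 18, 26), function(L) {
    a <- recist_annotation(ctr - c(L / 2, 0, 0), ctr + c(L / 2, 0, 0), 8)
    sum(build_sphere(a, recist_length(a), fl$vol, fl$lung)$mask)
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("seeded min-cut recovers a high-contrast blob (Dice > 0.8)", {
  # synthetic blob: lesion ~0 HU on ~-850 HU parenchyma
  dimg <- c(48L, 48L, 12L)
  sp <- c(1, 1, 2.5)
  vol0 <- image_volume(array(0, dimg), sp)
  ctr <- voxel_to_world(vol0, c(23.5, 23.5, 5.5))
  set.seed(31)
  truth <- ellipsoid_mask_for_test(vol0, ctr, c(10, 8, 7))
  data <- array(-850 + rnorm(prod(dimg), 0, 25), dimg)
  data[truth] <- 0 + rnorm(sum(truth), 0, 25)
  vol <- image_volume(data, sp)
  lung <- roi_mask(array(TRUE, dimg), vol, "lung")
  a <- derive_recist_line(roi_mask(truth, vol, "lesion"))
  solid <- segment_solid(a, vol, lung, ring_factor = 1.5)
  dice <- 2 * sum(solid$mask & truth) / (sum(solid$mask) + sum(truth))
  expect_gt(dice, 0.8)
  expect_false(isTRUE(attr(solid, "degenerate")))
})

test_that("degenerate and conflicting seed configurations are flagged", {
  dimg <- c(30L, 30L, 7L)
  vol <- image_volume(array(-500, dimg), c(1, 1, 2.5))
  lung <- roi_mask(array(TRUE, dimg), vol, "lung")
  a <- recist_annotation(c(10, 15, 7.5), c(20, 15, 7.5), 3)
  solid <- segment_solid(a, vol, lung)
  expect_true(isTRUE(attr(solid, "degenerate")))
  expect_true(any(solid$mask))
  # a ring smaller than the line must share voxels with it
  expect_error(segment_solid(a, vol, lung, ring_factor = 0.3), "overlap")
})

test_that("build_all_rois returns all six ROI kinds inside the lung", {
  coh <- generate_cohort(small_phantom_params(n_cases = 1, seed = 17))
  cs <- coh[[1]]
  rois <- build_all_rois(cs$recist_pd, cs$volume, cs$lung_mask)
  expect_setequal(names(rois),
                  c("lung_slice", "solid_ggo", "cylinder", "sphere20", "sphere40", "sphere_recist"))
  expect_named(rois$solid_ggo, c("solid", "ggo"))
  for (nm in setdiff(names(rois), "solid_ggo")) {
    expect_true(any(rois[[nm]]$mask))
    expect_true(all(cs$lung_mask$mask[rois[[nm]]$mask]))
  }
  expect_true(all(cs$lung_mask$mask[rois$solid_ggo$solid$mask]))
  expect_true(all(cs$lung_mask$mask[rois$solid_ggo$ggo$mask]))
  expect_false(any(rois$solid_ggo$ggo$mask & rois$solid_ggo$solid$mask))
})
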