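test_that("the shipped manifest pins the 20/21/11/24 feature memberships", {
  mf <- feature_manifest()
  expect_length(mf$first_order, 20)
  expect_length(mf$glcm, 21)
  expect_length(mf$glrlm, 11)
  expect_length(mf$shape, 24)
  expect_identical(mf$directions, c("d0", "d45", "d90", "d135", "avg"))
  # extraction output names follow the manifest exactly
  fl <- full_lung_volume(c(12L, 12L, 6L), c(1, 1, 2))
  set.seed(41)
  fl$vol$data[] <- rnorm(length(fl$vol$data), -500, 100)
  a <- recist_annotation(c(3, 5, 4), c(8, 5, 4), 2)
  f <- extract_features(fl$vol, build_sphere(a, 8, fl$vol, fl$lung))
  parts <- strsplit(names(f), "|", fixed = TRUE)
  fo <- vapply(parts[vapply(parts, `[[`, character(1), 2) == "firstorder"],
               `[[`, character(1), 3)
  expect_setequal(fo, mf$first_order)
  gl <- parts[vapply(parts, `[[`, character(1), 2) == "glcm"]
  expect_setequal(vapply(gl, `[[`, character(1), 3), mf$glcm)
  expect_setequal(vapply(gl, `[[`, character(1), 4), mf$directions)
})

test_that("first-order features match closed forms and a moment oracle", {
  dimg <- c(5L, 2L, 1L)
  vol <- image_volume(array(100, dimg), c(1, 1, 1))
  roi <- roi_mask(array(TRUE, dimg), vol, "sphere20")
  f <- first_order(vol, roi)
  expect_length(f, 20)
  expect_equal(unname(f["mean"]), 100)
  expect_equal(unname(f["std_dev"]), 0)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  expect_equal(unname(f["energy"]), 100^2 * 10)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["entropy"]), 0)

  vol2 <- image_volume(array(c(1, 2, 3, 4, 5), c(5, 1, 1)), c(1, 1, 1))
  roi2 <- roi_mask(array(TRUE, c(5, 1, 1)), vol2, "sphere20")
  f2 <- first_order(vol2, roi2)
  expect_equal(unname(f2["mean"]), 3)
  expect_equal(unname(f2["skewness"]), 0)
  expect_equal(unname(f2["total_intensity"]), 15)

  # third-central-moment oracle computed independently
  x <- c(1, 1, 1, 5)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  vol3 <- image_volume(array(x, c(4, 1, 1)), c(1, 1, 1))
  f3 <- first_order(vol3, roi_mask(array(TRUE, c(4, 1, 1)), vol3, "sphere20"))
  expect_equal(unname(f3["skewness"]), m3 / m2^1.5)

  # single-voxel ROI: dispersion features are 0 by convention
  one <- roi_mask(array(c(TRUE, rep(FALSE, 9)), c(5, 2, 1)), vol, "sphere20")
  f1 <- first_order(vol, one)
  expect_true(all(f1[c("variance", "std_dev", "skewness", "kurtosis", "iqr",
                       "mad", "rmad", "cv", "entropy")] == 0))
  expect_error(first_order(vol, roi_mask(array(FALSE, dimg), vol, "sphere20")), "empty")
})

test_that("GLCM accumulation matches closed forms and the pair-counting oracle", {
  # 1x2 ROI with equal levels: single diagonal entry 1
  lev <- array(NA_integer_, c(2, 1, 1)); lev[] <- c(3L, 3L)
  P <- glcm(NULL, NULL, c(1L, 0L, 0L), n_levels = 8, levels = lev)
  expect_equal(P[3, 3], 1)
  expect_equal(sum(P), 1)

  # two-level checkerboard, offset (1,0): all mass off-diagonal, split evenly
  cb <- array(NA_integer_, c(6, 6, 1))
  cb[] <- ifelse((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2 == 0, 1L, 2L)
  P2 <- glcm(NULL, NULL, c(1L, 0L, 0L), n_levels = 2, levels = cb)
  expect_equal(P2[1, 1] + P2[2, 2], 0)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)

  # random patches against the brute-force double loop, all four offsets
  set.seed(42)
  for (rep in 1:25) {
    d <- c(sample(3:9, 1), sample(3:9, 1), sample(1:3, 1))
    lev <- array(sample.int(6, prod(d), replace = TRUE), d)
    lev[sample(length(lev), length(lev) %/% 4)] <- NA  # irregular ROI
    for (off in list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))) {
      got <- tryCatch(glcm(NULL, NULL, off, n_levels = 6, levels = lev),
                      error = function(e) NULL)
      want <- brute_glcm(lev, c(off, 0)[1:3], 6)
      if (is.null(got)) {
        expect_true(all(is.nan(want)) || sum(want, na.rm = TRUE) == 0)
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
  expect_error(glcm(NULL, NULL, c(0L, 0L, 1L), levels = lev), "in-plane")
})

test_that("GLCM features match closed forms and independent summation", {
  P1 <- matrix(0, 4, 4); P1[2, 2] <- 1
  f1 <- glcm_features(P1)
  expect_length(f1, 21)
  expect_equal(unname(f1["maximum_probability"]), 1)
  expect_equal(unname(f1["joint_energy"]), 1)

  L <- 5
  Pu <- matrix(1 / L^2, L, L)
  fu <- glcm_features(Pu)
  expect_equal(unname(fu["maximum_probability"]), 1 / L^2)
  expect_equal(unname(fu["joint_energy"]), 1 / L^2)

  set.seed(43)
  M <- matrix(runif(36), 6, 6); M <- (M + t(M)); M <- M / sum(M)
  fM <- glcm_features(M)
  je <- 0
  for (i in 1:6) for (j in 1:6) je <- je + M[i, j]^2
  expect_equal(unname(fM["joint_energy"]), je)
  mx <- -Inf
  for (v in as.numeric(M)) mx <- max(mx, v)
  expect_equal(unname(fM["maximum_probability"]), mx)
  expect_error(glcm_features(M * 2), "normalized")
})

test_that("GLRLM runs match closed forms and the line-walking oracle", {
  # constant 1x5 row: one run of length 5; RP = 1/5
  lev <- array(NA_integer_, c(5, 1, 1)); lev[] <- 2L
  R <- glrlm(NULL, NULL, c(1L, 0L), n_levels = 4, levels = lev)
  expect_equal(sum(R), 1)
  expect_equal(R[2, 5], 1)
  f <- glrlm_features(R)
  expect_length(f, 11)
  expect_equal(unname(f["rp"]), 1 / 5)

  # alternating levels: all runs have length 1, SRE = 1
  lev2 <- array(rep(c(1L, 2L), 5), c(10, 1, 1))
  f2 <- glrlm_features(glrlm(NULL, NULL, c(1L, 0L), n_levels = 2, levels = lev2))
  expect_equal(unname(f2["sre"]), 1)
  expect_equal(unname(f2["rp"]), 1)

  set.seed(44)
  for (rep in 1:25) {
    d <- c(sample(3:9, 1), sample(3:9, 1), sample(1:3, 1))
    lev <- array(sample.int(4, prod(d), replace = TRUE), d)
    lev[sample(length(lev), length(lev) %/% 4)] <- NA
    for (dir in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
      got <- glrlm(NULL, NULL, dir, n_levels = 4, levels = lev)
      want <- brute_glrlm(lev, dir, 4)
      expect_equal(got[, seq_len(ncol(want))], want, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(got[, -seq_len(ncol(want))] == 0))
    }
  }
})

test_that("shape features match analytic solids", {
  # single voxel at 1 mm isotropic
  vol <- image_volume(array(0, c(5, 5, 5)), c(1, 1, 1))
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  f1 <- shape_features(roi_mask(m, vol, "solid"))
  expect_length(f1, 24)
  expect_equal(unname(f1["volume"]), 1)
  expect_equal(unname(f1["n_voxels"]), 1)

  # 10x10x10 voxel cube at 1 mm: V = 1000 mm^3, A ~ 600 mm^2,
  # sphericity ~ pi^(1/3) (6V)^(2/3) / 600
  volc <- image_volume(array(0, c(18, 18, 18)), c(1, 1, 1))
  mc <- array(FALSE, c(18, 18, 18)); mc[5:14, 5:14, 5:14] <- TRUE
  fc <- shape_features(roi_mask(mc, volc, "solid"))
  expect_equal(unname(fc["volume"]), 1000)
  # the face-weighted estimator under-measures sharp 90-degree edges by
  # up to ~9%; the analytic cube values are recovered to that accuracy
  expect_equal(unname(fc["surface_area"]), 600, tolerance = 0.10)
  expect_equal(unname(fc["sphericity"]), pi^(1 / 3) * (6 * 1000)^(2 / 3) / 600,
               tolerance = 0.10)
  expect_equal(unname(fc["max_3d_diameter"]), 9 * sqrt(3), tolerance = 1e-9)
  expect_equal(unname(fc["bbox_volume"]), 1000)
  expect_equal(unname(fc["extent"]), 1)
  expect_equal(unname(fc["elongation"]), 1, tolerance = 1e-9)

  # digital spheres: sphericity approaches 1 as the radius grows
  sph_sphericity <- function(r) {
    n <- 2 * r + 7
    vols <- image_volume(array(0, c(n, n, n)), c(1, 1, 1))
    ctr <- voxel_to_world(vols, rep((n - 1) / 2, 3))
    ms <- ellipsoid_mask_for_test(vols, ctr, rep(r, 3))
    unname(shape_features(roi_mask(ms, vols, "solid"))["sphericity"])
  }
  s <- vapply(c(6, 10, 16), sph_sphericity, numeric(1))
  expect_gt(s[3], 0.95)
  expect_lt(abs(s[3] - 1), 0.03)

  # 2D ROIs have no shape features
  roi2d <- roi_mask(m, vol, "lung_slice", two_d = TRUE)
  expect_error(shape_features(roi2d), "3D")
})

test_that("feature-vector contracts hold: 180 per ROI, 384 for solid+GGO, avg = mean", {
  coh <- generate_cohort(small_phantom_params(n_cases = 1, seed = 19))
  cs <- coh[[1]]
  rois <- build_all_rois(cs$recist_pd, cs$volume, cs$lung_mask)
  f_sphere <- extract_features(cs$volume, rois$sphere_recist)
  expect_length(f_sphere, 180)
  expect_true(all(is.finite(f_sphere)))
  f_pair <- extract_features(cs$volume, rois$solid_ggo)
  expect_length(f_pair, 384)
  expect_true(all(is.finite(f_pair)))
  # the avg direction is the mean of the four directional values
  mf <- feature_manifest()
  for (cls in c("glcm", "glrlm")) {
    fn <- if (cls == "glcm") mf$glcm else mf$glrlm
    for (feat in fn) {
      four <- f_sphere[paste("sphere_recist", cls, feat, c("d0", "d45", "d90", "d135"), sep = "|")]
      avg <- f_sphere[paste("sphere_recist", cls, feat, "avg", sep = "|")]
      expect_equal(unname(avg), mean(four), tolerance = 1e-12)
    }
  }
})

test_that("features are invariant to in-plane rotation up to direction relabeling", {
  set.seed(45)
  dimg <- c(14L, 14L, 4L)
  vol <- image_volume(array(rnorm(prod(dimg), -300, 150), dimg), c(1, 1, 1))
  m <- array(FALSE, dimg); m[4:11, 3:12, 2:3] <- TRUE
  roi <- roi_mask(m, vol, "sphere20")
  f <- extract_features(vol, roi)

  rot <- function(a) {
    # 90-degree in-plane rotation of a 3D array (x, y) -> (y, -x)
    b <- aperm(a, c(2, 1, 3))
    b[dim(b)[1]:1, , , drop = FALSE]
  }
  vol_r <- image_volume(rot(vol$data), c(1, 1, 1))
  roi_r <- roi_mask(rot(m), vol_r, "sphere20")
  f_r <- extract_features(vol_r, roi_r)

  mf <- feature_manifest()
  for (feat in mf$first_order) {
    expect_equal(unname(f[paste("sphere20", "firstorder", feat, sep = "|")]),
                 unname(f_r[paste("sphere20", "firstorder", feat, sep = "|")]),
                 tolerance = 1e-9)
  }
  # direction permutation under rotation: d0 <-> d90, d45 <-> d135
  map <- c(d0 = "d90", d45 = "d135", d90 = "d0", d135 = "d45", avg = "avg")
  for (cls in c("glcm", "glrlm")) {
    fn <- if (cls == "glcm") mf$glcm else mf$glrlm
    for (feat in fn) for (dn in names(map)) {
      expect_equal(
        unname(f[paste("sphere20", cls, feat, dn, sep = "|")]),
        unname(f_r[paste("sphere20", cls, feat, map[[dn]], sep = "|")]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("feature tables round-trip to CSV with a parameter sidecar", {
  coh <- generate_cohort(small_phantom_params(n_cases = 3, seed = 23))
  ft <- extract_cohort(coh, "sphere20")
  expect_identical(dim(ft$features), c(3L, 180L))
  expect_true(all(ft$volumes > 0))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "features.csv")
  write_feature_table(ft, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(nrow(back), 3L)
  expect_identical(ncol(back), 183L)  # id, label, volume + 180 features
  expect_equal(unname(as.matrix(back[, -(1:3)])), unname(ft$features), tolerance = 1e-12)
  side <- jsonlite::read_json(file.path(dir, "features_params.json"))
  expect_identical(side$roi_kind, "sphere20")
  expect_identical(side$n_levels, 32L)
})
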