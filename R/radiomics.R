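# Radiomic feature extraction: 20 first-order + (21 GLCM + 11 GLRLM) x
# 5 direction options = 180 features per ROI, plus 24 shape features on
# the solid sub-ROI. Texture matrices are computed in the four unique
# in-plane neighbour directions only (out-of-plane neighbours are
# excluded because of the strong slice anisotropy), and the fifth
# "direction" is the arithmetic mean of the four per-direction feature
# values. Intensities are discretized into `n_levels` equal-width bins
# over the ROI min-max before any matrix is accumulated.

glcm_offsets <- function() {
  list(d0 = c(1L, 0L, 0L), d45 = c(1L, 1L, 0L), d90 = c(0L, 1L, 0L), d135 = c(-1L, 1L, 0L))
}

#' Equal-width discretization of ROI intensities
#'
#' @param x numeric vector or array of intensities.
#' @param n_levels number of gray levels (>= 2); default 32.
#' @param lo,hi discretization range; defaults to the ROI min-max.
#' @return integer levels in `1..n_levels` (`NA` where `x` is `NA`).
#' @export
discretize <- function(x, n_levels = 32L, lo = NULL, hi = NULL) {
  if (n_levels < 2L) stopf("`n_levels` must be >= 2")
  lo <- lo %||% min(x, na.rm = TRUE)
  hi <- hi %||% max(x, na.rm = TRUE)
  if (hi <= lo) {
    lev <- ifelse(is.na(x), NA_integer_, 1L)
  } else {
    lev <- pmin(n_levels, floor((x - lo) / (hi - lo) * n_levels) + 1L)
  }
  if (is.array(x)) array(as.integer(lev), dim(x)) else as.integer(lev)
}

first_order_names <- function() {
  c(
    "mean", "median", "minimum", "maximum", "range", "variance", "std_dev",
    "skewness", "kurtosis", "energy", "entropy", "uniformity", "p10", "p90",
    "iqr", "mad", "rmad", "rms", "cv", "total_intensity"
  )
}

#' First-order (histogram) features of the raw HU values in an ROI
#'
#' Computed on the raw intensity multiset; `entropy` and `uniformity`
#' use the discretized histogram. Moments are population moments
#' (denominator n); skewness is the third standardized central moment
#' and kurtosis the fourth (not excess). Dispersion features of a
#' constant or single-voxel ROI are defined as 0 (uniformity 1).
#'
#' @param vol an [image_volume()].
#' @param roi a `roi_mask` on the same grid.
#' @param n_levels discretization levels for entropy/uniformity.
#' @return named numeric vector of exactly 20 features.
#' @export
first_order <- function(vol, roi, n_levels = 32L) {
  stopifnot(inherits(roi, "roi_mask"))
  x <- vol$data[roi$mask]
  if (!length(x)) stopf("ROI is empty")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  lev <- discretize(x, n_levels)
  p <- tabulate(lev, n_levels) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  inner <- x[x >= q[1] & x <= q[4]]
  out <- c(
    mean = mu,
    median = stats::median(x),
    minimum = min(x),
    maximum = max(x),
    range = max(x) - min(x),
    variance = m2,
    std_dev = sdv,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2],
    mad = mean(abs(x - mu)),
    rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    rms = sqrt(mean(x^2)),
    cv = if (mu != 0) sdv / abs(mu) else 0,
    total_intensity = sum(x)
  )
  out[first_order_names()]
}

#' Gray-level co-occurrence matrix for one in-plane offset
#'
#' Counts level pairs `(v(p), v(p + offset))` with both voxels inside
#' the ROI, accumulated symmetrically (both orderings), normalized to
#' sum 1.
#'
#' @param vol an [image_volume()] (or `NULL` when `levels` is given).
#' @param roi a `roi_mask`.
#' @param offset integer voxel offset, one of `(1,0,0)`, `(1,1,0)`,
#'   `(0,1,0)`, `(-1,1,0)`.
#' @param n_levels discretization levels.
#' @param levels optional pre-discretized level array (NA outside ROI);
#'   overrides `vol`/`roi`.
#' @return `n_levels x n_levels` normalized matrix.
#' @export
glcm <- function(vol, roi, offset, n_levels = 32L, levels = NULL) {
  if (is.null(levels)) {
    stopifnot(inherits(roi, "roi_mask"))
    if (sum(roi$mask) < 2L) stopf("ROI must contain at least 2 voxels")
    levels <- level_array(vol, roi, n_levels)
  }
  offs <- glcm_offsets()
  ok <- any(vapply(offs, function(o) all(o == offset), logical(1)))
  if (!ok) stopf("`offset` must be one of the four unique in-plane directions")
  ab <- shifted_pairs(levels, offset)
  if (!nrow(ab)) stopf("no valid voxel pairs for offset (%d,%d,%d)", offset[1], offset[2], offset[3])
  counts <- tabulate((ab[, 1] - 1L) * n_levels + ab[, 2], n_levels * n_levels)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

# level array: discretized intensities inside the ROI, NA elsewhere
level_array <- function(vol, roi, n_levels) {
  x <- array(NA_real_, dim(vol$data))
  x[roi$mask] <- vol$data[roi$mask]
  discretize(x, n_levels)
}

# all (a, b) level pairs for a voxel offset, both ends inside the ROI
shifted_pairs <- function(levels, offset) {
  d <- dim(levels)
  rng <- function(n, o) if (o >= 0) seq_len(n - o) else seq(1 - o, n)
  ia <- rng(d[1], offset[1]); ja <- rng(d[2], offset[2]); ka <- rng(d[3], offset[3])
  a <- levels[ia, ja, ka, drop = FALSE]
  b <- levels[ia + offset[1], ja + offset[2], ka + offset[3], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

glcm_feature_names <- function() {
  c(
    "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "joint_energy",
    "joint_entropy", "idm", "id", "inverse_variance", "maximum_probability",
    "sum_average", "sum_entropy", "sum_squares", "imc1"
  )
}

#' The 21 GLCM features from a normalized co-occurrence matrix
#'
#' Includes the maximum probability (`maximum_probability`, the largest
#' matrix entry) and the joint energy (`joint_energy`, the sum of
#' squared entries). Entropies are in bits.
#'
#' @param P normalized co-occurrence matrix (sums to 1).
#' @return named numeric vector of exactly 21 features.
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stopf("co-occurrence matrix must be normalized to sum 1")
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  s_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  s_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  # diagonal and cross-diagonal marginals
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * L)
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kd <- 0:(L - 1)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  autoc <- sum(i * j * P)
  corr <- if (s_x > 0 && s_y > 0) (autoc - mu_x * mu_y) / (s_x * s_y) else 1
  diff_avg <- sum(kd * pdiff)
  HX <- ent(px); HY <- ent(py); HXY <- ent(P)
  pxy <- outer(px, py)
  sel <- P > 0 & pxy > 0
  HXY1 <- -sum(P[sel] * log2(pxy[sel]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  out <- c(
    autocorrelation = autoc,
    joint_average = sum(i * P),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = diff_avg,
    difference_entropy = ent(pdiff),
    difference_variance = sum((kd - diff_avg)^2 * pdiff),
    dissimilarity = sum(abs(i - j) * P),
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    idm = sum(P / (1 + (i - j)^2)),
    id = sum(P / (1 + abs(i - j))),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(P),
    sum_average = sum(ks * psum),
    sum_entropy = ent(psum),
    sum_squares = sum((i - mu_x)^2 * P),
    imc1 = imc1
  )
  out[glcm_feature_names()]
}

#' Gray-level run-length matrix for one in-plane direction
#'
#' Runs of consecutive equal levels are counted per axial slice along
#' the given in-plane direction; runs are truncated at the ROI boundary
#' (a voxel outside the ROI breaks the run).
#'
#' @inheritParams glcm
#' @param direction integer in-plane direction `(dx, dy)`, one of
#'   `(1,0)`, `(0,1)`, `(1,1)`, `(-1,1)`.
#' @return matrix `n_levels x max_run_length` of run counts.
#' @export
glrlm <- function(vol, roi, direction, n_levels = 32L, levels = NULL) {
  if (is.null(levels)) {
    stopifnot(inherits(roi, "roi_mask"))
    levels <- level_array(vol, roi, n_levels)
  }
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  if (!any(vapply(dirs, function(d) all(d == direction[1:2]), logical(1)))) {
    stopf("`direction` must be an in-plane direction (1,0), (0,1), (1,1) or (-1,1)")
  }
  d <- dim(levels)
  maxlen <- max(d[1], d[2])
  R <- matrix(0, n_levels, maxlen)
  ij <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  key <- switch(paste(direction[1], direction[2]),
    "1 0" = ij[, 2], "0 1" = ij[, 1],
    "1 1" = ij[, 1] - ij[, 2], "-1 1" = ij[, 1] + ij[, 2]
  )
  tpos <- switch(paste(direction[1], direction[2]),
    "1 0" = ij[, 1], "0 1" = ij[, 2], "1 1" = ij[, 1], "-1 1" = ij[, 2]
  )
  ord <- order(key, tpos)
  key_ord <- key[ord]
  grp <- cumsum(c(1L, as.integer(diff(key_ord) != 0)))
  base <- as.numeric(n_levels + 1L)
  for (k in seq_len(d[3])) {
    v <- as.integer(levels[, , k])[ord]
    v[is.na(v)] <- 0L
    combined <- v + grp * base
    r <- rle(combined)
    val <- as.integer(r$values %% base)
    keep <- val > 0L
    if (!any(keep)) next
    lens <- r$lengths[keep]
    vals <- val[keep]
    inc <- table(factor(vals, levels = seq_len(n_levels)),
                 factor(pmin(lens, maxlen), levels = seq_len(maxlen)))
    R <- R + unclass(inc)
  }
  if (sum(R) == 0) stopf("ROI contains no runs for direction (%d,%d)", direction[1], direction[2])
  R
}

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "rln", "rp", "lglre", "hglre",
    "srlgle", "srhgle", "lrlgle", "lrhgle")
}

#' The 11 classical GLRLM features
#'
#' Short/long run emphasis, gray-level and run-length non-uniformity,
#' run percentage, and the low/high gray-level (short/long run) emphasis
#' family.
#'
#' @param R run-length count matrix (levels x run length).
#' @return named numeric vector of exactly 11 features.
#' @export
glrlm_features <- function(R) {
  Nr <- sum(R)
  if (Nr == 0) stopf("empty run-length matrix")
  i <- row(R); j <- col(R)
  Np <- sum(j * R)
  out <- c(
    sre = sum(R / j^2) / Nr,
    lre = sum(R * j^2) / Nr,
    gln = sum(rowSums(R)^2) / Nr,
    rln = sum(colSums(R)^2) / Nr,
    rp = Nr / Np,
    lglre = sum(R / i^2) / Nr,
    hglre = sum(R * i^2) / Nr,
    srlgle = sum(R / (i^2 * j^2)) / Nr,
    srhgle = sum(R * i^2 / j^2) / Nr,
    lrlgle = sum(R * j^2 / i^2) / Nr,
    lrhgle = sum(R * i^2 * j^2) / Nr
  )
  out[glrlm_feature_names()]
}

shape_feature_names <- function() {
  c(
    "volume", "n_voxels", "surface_area", "surface_to_volume", "sphericity",
    "compactness1", "compactness2", "spherical_disproportion",
    "max_3d_diameter", "max_2d_diameter_axial", "max_2d_diameter_coronal",
    "max_2d_diameter_sagittal", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness", "bbox_dim_x", "bbox_dim_y",
    "bbox_dim_z", "bbox_volume", "extent", "equiv_sphere_diameter",
    "radius_of_gyration"
  )
}

#' The 24 shape features of a 3D mask, in mm
#'
#' Volume is voxel-counting volume; surface area is estimated by the
#' coarea formula (integral of the gradient magnitude of a Gaussian-
#' smoothed indicator, kernel sd one voxel per axis), which measures
#' flat faces exactly and converges to the true area for smooth shapes.
#' Maximum 3D and per-plane 2D diameters are exact pairwise distances
#' over boundary voxel centers. Principal axis lengths are
#' `4 * sqrt(eigenvalue)` of the voxel-center covariance.
#'
#' @param mask a 3D `roi_mask` (errors on 2D ROIs).
#' @return named numeric vector of exactly 24 features.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (mask$two_d) stopf("shape features are only defined for 3D (solid) ROIs")
  m <- mask$mask
  if (!any(m)) stopf("mask is empty")
  sp <- mask$spacing
  voxvol <- prod(sp)
  n <- sum(m)
  V <- n * voxvol
  A <- face_weighted_surface(m, sp)
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(
    (idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 3] - 1) * sp[3]
  )
  bd3 <- boundary_points(m, sp)
  d3 <- farthest_pair(bd3)$dist
  d_ax <- proj_diameter(m, sp, drop_axis = 3)
  d_cor <- proj_diameter(m, sp, drop_axis = 2)
  d_sag <- proj_diameter(m, sp, drop_axis = 1)
  cen <- colMeans(pts)
  rel <- sweep(pts, 2, cen)
  if (n > 1) {
    ev <- sort(eigen(stats::cov(rel), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  bbox <- unname((hi - lo + 1) * sp)
  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  out <- c(
    volume = V,
    n_voxels = n,
    surface_area = A,
    surface_to_volume = A / V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness1 = V / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * r_eq^2),
    max_3d_diameter = d3,
    max_2d_diameter_axial = d_ax,
    max_2d_diameter_coronal = d_cor,
    max_2d_diameter_sagittal = d_sag,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    elongation = elong,
    flatness = flat,
    bbox_dim_x = bbox[1],
    bbox_dim_y = bbox[2],
    bbox_dim_z = bbox[3],
    bbox_volume = prod(bbox),
    extent = V / prod(bbox),
    equiv_sphere_diameter = 2 * r_eq,
    radius_of_gyration = sqrt(mean(rowSums(rel^2)))
  )
  out[shape_feature_names()]
}

# Surface area by gradient-weighted exposed-face counting. Each exposed
# voxel face contributes its face area times |n . e|, where n is the
# local surface normal estimated from the gradient of a Gaussian-smoothed
# indicator and e the face axis. For a flat surface of any orientation
# the weights sum exactly to the true area (plain face counting
# overestimates oblique surfaces by up to sqrt(3)); for smooth shapes the
# estimate converges to the true area with grid refinement.
face_weighted_surface <- function(m, sp) {
  pad <- 4L
  d <- dim(m)
  dp <- d + 2L * pad
  u <- array(0, dp)
  u[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- as.numeric(m)
  us <- smooth_gaussian(u, c(1, 1, 1))
  # central-difference gradient per voxel of the padded grid interior
  grad <- function(ax) {
    g <- array(0, dp)
    idx_mid <- lapply(seq_len(3), function(i) if (i == ax) 2:(dp[i] - 1) else seq_len(dp[i]))
    idx_hi <- lapply(seq_len(3), function(i) if (i == ax) 3:dp[i] else seq_len(dp[i]))
    idx_lo <- lapply(seq_len(3), function(i) if (i == ax) 1:(dp[i] - 2) else seq_len(dp[i]))
    g <- do.call(`[<-`, c(list(g), idx_mid, list(
      value = (do.call(`[`, c(list(us), idx_hi, list(drop = FALSE))) -
                 do.call(`[`, c(list(us), idx_lo, list(drop = FALSE)))) / (2 * sp[ax])
    )))
    g
  }
  gx <- grad(1); gy <- grad(2); gz <- grad(3)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  total <- 0
  for (ax in 1:3) {
    g_ax <- switch(ax, gx, gy, gz)
    lo <- lapply(seq_len(3), function(i) if (i == ax) 1:(dp[i] - 1) else seq_len(dp[i]))
    hi <- lapply(seq_len(3), function(i) if (i == ax) 2:dp[i] else seq_len(dp[i]))
    a <- do.call(`[`, c(list(u), lo, list(drop = FALSE)))
    b <- do.call(`[`, c(list(u), hi, list(drop = FALSE)))
    exposed <- a != b
    if (!any(exposed)) next
    # face normal weight: |g . e| / |g| averaged over the two flanking voxels
    w_of <- function(garr, marr) {
      ga <- do.call(`[`, c(list(garr), lo, list(drop = FALSE)))
      gb <- do.call(`[`, c(list(garr), hi, list(drop = FALSE)))
      ma <- do.call(`[`, c(list(marr), lo, list(drop = FALSE)))
      mb <- do.call(`[`, c(list(marr), hi, list(drop = FALSE)))
      list(g = (ga + gb) / 2, m = (ma + mb) / 2)
    }
    wa <- w_of(g_ax, gmag)
    w <- abs(wa$g[exposed]) / pmax(wa$m[exposed], 1e-12)
    w[wa$m[exposed] < 1e-12] <- 1
    face_area <- prod(sp[-ax])
    total <- total + sum(pmin(w, 1)) * face_area
  }
  total
}

boundary_points <- function(m, sp) {
  d <- dim(m)
  nb <- array(0L, d)
  add <- function(ax, sgn) {
    shifted <- array(FALSE, d)
    if (ax == 1 && sgn > 0) shifted[-d[1], , ] <- m[-1, , ]
    if (ax == 1 && sgn < 0) shifted[-1, , ] <- m[-d[1], , ]
    if (ax == 2 && sgn > 0) shifted[, -d[2], ] <- m[, -1, ]
    if (ax == 2 && sgn < 0) shifted[, -1, ] <- m[, -d[2], ]
    if (ax == 3 && sgn > 0) shifted[, , -d[3]] <- m[, , -1]
    if (ax == 3 && sgn < 0) shifted[, , -1] <- m[, , -d[3]]
    shifted
  }
  for (ax in 1:3) for (sgn in c(1, -1)) nb <- nb + add(ax, sgn)
  bd <- m & nb < 6L
  idx <- which(bd, arr.ind = TRUE)
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 3] - 1) * sp[3])
}

proj_diameter <- function(m, sp, drop_axis) {
  pr <- apply(m, setdiff(1:3, drop_axis), any)
  d2 <- dim(pr)
  nb <- matrix(0L, d2[1], d2[2])
  nb[-1, ] <- nb[-1, ] + pr[-d2[1], ]
  nb[-d2[1], ] <- nb[-d2[1], ] + pr[-1, ]
  nb[, -1] <- nb[, -1] + pr[, -d2[2]]
  nb[, -d2[2]] <- nb[, -d2[2]] + pr[, -1]
  bd <- which(pr & nb < 4L, arr.ind = TRUE)
  sp2 <- sp[setdiff(1:3, drop_axis)]
  pts <- cbind((bd[, 1] - 1) * sp2[1], (bd[, 2] - 1) * sp2[2])
  farthest_pair(pts)$dist
}

#' Extract the full feature vector for one ROI (or the solid+GGO pair)
#'
#' Single-ROI kinds yield exactly 180 named features
#' (`<roi>|<class>|<feature>[|<direction>]`); the solid+GGO pair yields
#' 180 + 180 + 24 shape features on the solid = 384. The `avg` direction
#' is the arithmetic mean of the four per-direction feature values.
#'
#' @param vol the (resampled) [image_volume()].
#' @param rois a single `roi_mask`, or a list with elements `solid` and
#'   `ggo` for the solid+GGO ROI.
#' @param n_levels discretization levels (default 32).
#' @return named numeric vector of 180 or 384 features.
#' @export
extract_features <- function(vol, rois, n_levels = 32L) {
  if (inherits(rois, "roi_mask")) {
    return(texture_set(vol, rois, rois$kind, n_levels))
  }
  if (is.list(rois) && all(c("solid", "ggo") %in% names(rois))) {
    solid <- texture_set(vol, rois$solid, "solid", n_levels)
    ggo <- texture_set(vol, rois$ggo, "ggo", n_levels)
    shp <- shape_features(rois$solid)
    names(shp) <- paste("solid", "shape", shape_feature_names(), sep = "|")
    return(c(solid, ggo, shp))
  }
  stopf("`rois` must be a roi_mask or a list(solid=, ggo=)")
}

texture_set <- function(vol, roi, prefix, n_levels) {
  fo <- first_order(vol, roi, n_levels)
  names(fo) <- paste(prefix, "firstorder", first_order_names(), sep = "|")
  levels <- level_array(vol, roi, n_levels)
  dirs <- glcm_offsets()
  dir_names <- names(dirs)
  gl <- lapply(dir_names, function(dn) {
    P <- tryCatch(
      glcm(NULL, NULL, dirs[[dn]], n_levels, levels = levels),
      error = function(e) stopf("GLCM %s failed for '%s': %s", dn, prefix, conditionMessage(e))
    )
    glcm_features(P)
  })
  rl <- lapply(dir_names, function(dn) {
    R <- tryCatch(
      glrlm(NULL, NULL, dirs[[dn]][1:2], n_levels, levels = levels),
      error = function(e) stopf("GLRLM %s failed for '%s': %s", dn, prefix, conditionMessage(e))
    )
    glrlm_features(R)
  })
  pack <- function(per_dir, class, fnames) {
    mat <- do.call(cbind, per_dir)          # features x 4 directions
    avg <- rowMeans(mat)
    vals <- c(as.numeric(mat), avg)
    nms <- c(
      as.vector(outer(fnames, dir_names, function(f, d) paste(prefix, class, f, d, sep = "|"))),
      paste(prefix, class, fnames, "avg", sep = "|")
    )
    stats::setNames(vals, nms)
  }
  c(fo, pack(gl, "glcm", glcm_feature_names()), pack(rl, "glrlm", glrlm_feature_names()))
}

#' Extract a cohort-level feature table for one ROI kind
#'
#' For each phantom case: resample the progressive-disease scan to the
#' common grid (if not already on it), rebuild the lung mask on that
#' grid from mm-space geometry, build the requested ROI from the RECIST
#' annotation, and extract the feature vector. Also records each case's
#' ROI volume in mm^3 (solid + GGO combined for the pair).
#'
#' @param cohort list of `phantom_case`.
#' @param roi_kind one of [roi_kinds()].
#' @param target_spacing common voxel grid, mm (default the most common
#'   scanner spacing, 0.74 x 0.74 x 5.00).
#' @param n_levels discretization levels.
#' @param cylinder_radius,ggo_expansion,ring_factor ROI parameters.
#' @return An object of class `feature_table`: list with `features`
#'   (cases x features matrix), `labels` (factor, positive class
#'   `recurrence`), `volumes` (mm^3), `case_ids`, `roi_kind`, and the
#'   extraction parameters.
#' @export
extract_cohort <- function(cohort, roi_kind, target_spacing = c(0.74, 0.74, 5.0),
                           n_levels = 32L, cylinder_radius = 10, ggo_expansion = 16,
                           ring_factor = 1.5) {
  roi_kind <- match.arg(roi_kind, roi_kinds())
  rows <- lapply(cohort, function(cs) {
    vol <- cs$volume
    if (max(abs(vol$spacing - target_spacing)) > 1e-9) {
      vol <- resample(vol, target_spacing)
    }
    lung <- lung_mask_on_grid(cs, vol)
    a <- cs$recist_pd
    rois <- switch(roi_kind,
      lung_slice = build_lung_slice(a, vol, lung),
      cylinder = build_cylinder(a, cylinder_radius, vol, lung),
      sphere20 = build_sphere(a, 20, vol, lung),
      sphere40 = build_sphere(a, 40, vol, lung),
      sphere_recist = build_sphere(a, recist_length(a), vol, lung),
      solid_ggo = {
        solid <- segment_solid(a, vol, lung, ring_factor = ring_factor)
        list(solid = solid, ggo = expand_ggo(solid, ggo_expansion, lung))
      }
    )
    voxvol <- prod(vol$spacing)
    volume_mm3 <- if (inherits(rois, "roi_mask")) sum(rois$mask) * voxvol
                  else (sum(rois$solid$mask) + sum(rois$ggo$mask)) * voxvol
    list(f = extract_features(vol, rois, n_levels), v = volume_mm3)
  })
  feats <- do.call(rbind, lapply(rows, `[[`, "f"))
  rownames(feats) <- vapply(cohort, function(cs) sprintf("case%03d", cs$case_id), character(1))
  structure(
    list(
      features = feats,
      labels = factor(vapply(cohort, `[[`, character(1), "label"),
                      levels = c("rili", "recurrence")),
      volumes = vapply(rows, `[[`, numeric(1), "v"),
      case_ids = vapply(cohort, `[[`, integer(1), "case_id"),
      roi_kind = roi_kind,
      params = list(target_spacing = target_spacing, n_levels = n_levels)
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d cases x %d features (ROI %s, %d recurrence / %d RILI)\n",
    nrow(x$features), ncol(x$features), x$roi_kind,
    sum(x$labels == "recurrence"), sum(x$labels == "rili")
  ))
  invisible(x)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path; the JSON sidecar (if present) restores the
#'   extraction parameters.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("case_id", "label", "roi_volume_mm3")
  if (!all(need %in% colnames(df))) {
    stopf("not a feature table CSV (missing %s)", paste(setdiff(need, colnames(df)), collapse = ", "))
  }
  feats <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  rownames(feats) <- sprintf("case%03d", df$case_id)
  side_path <- paste0(sub("\\.csv$", "", path), "_params.json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  structure(
    list(
      features = feats,
      labels = factor(df$label, levels = c("rili", "recurrence")),
      volumes = df$roi_volume_mm3,
      case_ids = df$case_id,
      roi_kind = side$roi_kind %||% NA_character_,
      params = side[setdiff(names(side), c("roi_kind", "n_cases", "n_features"))]
    ),
    class = "feature_table"
  )
}

#' The frozen feature manifest shipped with the package
#'
#' Versioned list of the exact feature-name membership (20 first-order,
#' 21 GLCM, 11 GLRLM, 24 shape) and the direction labels; the extraction
#' code and the tests both pin against it.
#'
#' @return named list as stored in `inst/extdata/feature_manifest.json`.
#' @export
feature_manifest <- function() {
  path <- system.file("extdata", "feature_manifest.json", package = "sabradiomics")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a feature table as CSV with a JSON parameter sidecar
#'
#' @param ft a `feature_table`.
#' @param path CSV destination; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(
    case_id = ft$case_ids, label = as.character(ft$labels),
    roi_volume_mm3 = ft$volumes, check.names = FALSE
  )
  df <- cbind(df, as.data.frame(ft$features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    c(ft$params, list(roi_kind = ft$roi_kind, n_cases = nrow(ft$features),
                      n_features = ncol(ft$features))),
    paste0(side, "_params.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
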