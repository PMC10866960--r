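# The six regions of interest, all constructed from a RECIST annotation,
# a CT volume and a lung mask, in mm world space on the volume's grid.
# Inclusion rule throughout: a voxel belongs to a region iff its *center*
# lies inside the region (no partial-volume weighting). Every ROI is
# intersected with the lung mask.

#' The six ROI kinds of the analysis
#' @return character vector of ROI kind identifiers.
#' @export
roi_kinds <- function() {
  c("lung_slice", "solid_ggo", "cylinder", "sphere20", "sphere40", "sphere_recist")
}

check_roi_inputs <- function(a, vol, lung) {
  stopifnot(inherits(a, "recist_annotation"), inherits(vol, "image_volume"),
            inherits(lung, "roi_mask"))
  if (!identical(dim(lung$mask), dim(vol$data))) {
    stopf("lung mask grid does not match the volume grid")
  }
}

#' Spherical ROI centered on the RECIST line midpoint
#'
#' A voxel is included iff its center lies within `diameter / 2` mm of
#' the RECIST midpoint (anisotropic world-space distance), intersected
#' with the lung mask.
#'
#' @param a a [recist_annotation()].
#' @param diameter sphere diameter in mm (20, 40, or the RECIST length).
#' @param vol the [image_volume()] supplying the grid.
#' @param lung the lung `roi_mask`.
#' @return A `roi_mask` (kind `sphere20`, `sphere40` or `sphere_recist`
#'   by diameter).
#' @export
build_sphere <- function(a, diameter, vol, lung) {
  check_roi_inputs(a, vol, lung)
  if (diameter <= 0) stopf("`diameter` must be > 0")
  M <- recist_midpoint(a)
  r <- diameter / 2
  dx2 <- (axis_coords(vol, 1) - M[1])^2
  dy2 <- (axis_coords(vol, 2) - M[2])^2
  dz2 <- (axis_coords(vol, 3) - M[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2 + 1e-9
  if (!any(inside)) {
    # sub-voxel sphere: the voxel containing the midpoint
    idx <- round(world_to_voxel(vol, M))
    if (all(idx >= 0) && all(idx <= dim(vol$data) - 1)) {
      inside[idx[1] + 1, idx[2] + 1, idx[3] + 1] <- TRUE
    }
  }
  inside <- inside & lung$mask
  if (!any(inside)) stopf("sphere ROI is empty after lung intersection")
  kind <- if (isTRUE(all.equal(diameter, 20))) "sphere20"
          else if (isTRUE(all.equal(diameter, 40))) "sphere40"
          else "sphere_recist"
  roi_mask(inside, vol, kind)
}

#' Cylindrical ROI with the RECIST line as rotation axis
#'
#' A voxel is included iff the perpendicular distance from its center to
#' the 3D line through the RECIST endpoints is at most `radius` mm AND
#' its projection onto the line falls within the segment (flat ends, not
#' capsule caps), intersected with the lung mask.
#'
#' @inheritParams build_sphere
#' @param radius cylinder radius in mm (default 10).
#' @return A `roi_mask` of kind `"cylinder"`.
#' @export
build_cylinder <- function(a, radius = 10, vol, lung) {
  check_roi_inputs(a, vol, lung)
  L <- recist_length(a)
  if (L <= 0) stopf("RECIST length must be > 0 for a cylinder ROI")
  if (radius <= 0) stopf("`radius` must be > 0")
  u <- (a$p2 - a$p1) / L
  d <- dim(vol$data)
  # bounding box of the capsule to limit the scan
  lo_w <- pmin(a$p1, a$p2) - radius
  hi_w <- pmax(a$p1, a$p2) + radius
  lo <- pmax(floor(world_to_voxel(vol, lo_w)), 0)
  hi <- pmin(ceiling(world_to_voxel(vol, hi_w)), d - 1)
  inside <- array(FALSE, d)
  if (all(lo <= hi)) {
    ix <- (lo[1]:hi[1]); iy <- (lo[2]:hi[2]); iz <- (lo[3]:hi[3])
    g <- expand.grid(
      x = vol$origin[1] + ix * vol$spacing[1],
      y = vol$origin[2] + iy * vol$spacing[2],
      z = vol$origin[3] + iz * vol$spacing[3]
    )
    rel <- cbind(g$x - a$p1[1], g$y - a$p1[2], g$z - a$p1[3])
    t <- rel %*% u
    perp2 <- rowSums(rel^2) - t^2
    ok <- t >= -1e-9 & t <= L + 1e-9 & perp2 <= radius^2 + 1e-9
    sub <- array(ok, dim = c(length(ix), length(iy), length(iz)))
    inside[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1] <- sub
  }
  inside <- inside & lung$mask
  if (!any(inside)) stopf("cylinder ROI is empty after lung intersection")
  roi_mask(inside, vol, "cylinder")
}

#' 2D lung-slice ROI on the RECIST slice
#'
#' The segmented lung restricted to the axial slice where the RECIST
#' line was drawn (the slice index is recovered from the line's world z
#' through [world_to_voxel()]). Flagged 2D so shape features are
#' skipped.
#'
#' @inheritParams build_sphere
#' @return A `roi_mask` of kind `"lung_slice"` with `two_d = TRUE`.
#' @export
build_lung_slice <- function(a, vol, lung) {
  check_roi_inputs(a, vol, lung)
  k <- round(world_to_voxel(vol, a$p1)[3]) + 1
  if (k < 1 || k > dim(vol$data)[3]) stopf("RECIST slice lies outside the volume")
  out <- array(FALSE, dim(vol$data))
  out[, , k] <- lung$mask[, , k]
  if (!any(out)) stopf("lung mask is empty in the RECIST slice")
  roi_mask(out, vol, "lung_slice", two_d = TRUE)
}

# 3D Bresenham-style rasterisation of the segment p1-p2 into 0-based
# voxel indices: uniform sampling at one step per dominant-axis voxel,
# rounded to centers (deduplicated, connected for in-plane lines).
rasterize_line <- function(vol, p1, p2) {
  i1 <- world_to_voxel(vol, p1)
  i2 <- world_to_voxel(vol, p2)
  n <- max(abs(round(i2) - round(i1))) + 1
  t <- seq(0, 1, length.out = max(n, 2))
  pts <- round(cbind(
    i1[1] + t * (i2[1] - i1[1]),
    i1[2] + t * (i2[2] - i1[2]),
    i1[3] + t * (i2[3] - i1[3])
  ))
  unique(pts)
}

#' Solid sub-ROI by seeded min-cut segmentation
#'
#' A stand-in for interactive OneCut segmentation preserving its
#' interface: the rasterized RECIST line provides hard foreground seeds
#' and a circle of radius `ring_factor * length / 2` in the RECIST slice
#' provides hard background seeds. The cut is a max-flow/min-cut on the
#' 6-connected voxel graph over a box around the ring, with pairwise
#' capacities `exp(-dI^2 / (2 sigma^2))`; `sigma` is estimated from
#' intensity differences in the one-voxel-dilated seed neighbourhood.
#' The returned mask is the foreground connected component containing
#' the line, intersected with the lung.
#'
#' @inheritParams build_sphere
#' @param ring_factor background ring radius as a multiple of the RECIST
#'   half-length (> 1 so the ring clears the line).
#' @param cap_epsilon edges with capacity below this are dropped before
#'   the max-flow solve; such edges lie where a cut is essentially free
#'   (strong intensity steps), so the partition is unchanged up to
#'   boundary voxels while the solve is several times faster. Any region
#'   thereby disconnected from the line is removed by the
#'   component-selection step.
#' @return A `roi_mask` of kind `"solid"`. If the image is uniform the
#'   cut is degenerate (seeds' partition); the result then carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
segment_solid <- function(a, vol, lung, ring_factor = 1.5, cap_epsilon = 1e-5) {
  check_roi_inputs(a, vol, lung)
  L <- recist_length(a)
  if (L <= 0) stopf("RECIST length must be > 0")
  d <- dim(vol$data)
  M <- recist_midpoint(a)
  ring_r <- ring_factor * L / 2

  # box: ring radius + 2 voxels in-plane, lesion-scale in z
  half <- c(ring_r + 2 * vol$spacing[1], ring_r + 2 * vol$spacing[2], L / 2 + 2 * vol$spacing[3])
  lo <- pmax(floor(world_to_voxel(vol, M - half)), 0)
  hi <- pmin(ceiling(world_to_voxel(vol, M + half)), d - 1)
  bd <- hi - lo + 1
  sub <- vol$data[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1, drop = FALSE]

  # seeds in box-local 1-based indices
  line_idx <- rasterize_line(vol, a$p1, a$p2)
  line_idx <- sweep(line_idx, 2, lo, "-") + 1
  keep <- line_idx[, 1] >= 1 & line_idx[, 1] <= bd[1] &
    line_idx[, 2] >= 1 & line_idx[, 2] <= bd[2] &
    line_idx[, 3] >= 1 & line_idx[, 3] <= bd[3]
  line_idx <- line_idx[keep, , drop = FALSE]
  if (!nrow(line_idx)) stopf("RECIST line lies outside the volume")

  theta <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * ring_r / min(vol$spacing[1:2]))))
  ring_w <- cbind(M[1] + ring_r * cos(theta), M[2] + ring_r * sin(theta), M[3])
  ring_idx <- round(world_to_voxel(vol, ring_w))
  ring_idx <- sweep(ring_idx, 2, lo, "-") + 1
  keep <- ring_idx[, 1] >= 1 & ring_idx[, 1] <= bd[1] &
    ring_idx[, 2] >= 1 & ring_idx[, 2] <= bd[2] &
    ring_idx[, 3] >= 1 & ring_idx[, 3] <= bd[3]
  ring_idx <- unique(ring_idx[keep, , drop = FALSE])
  if (!nrow(ring_idx)) stopf("background ring lies entirely outside the volume")

  lin <- function(ix) (ix[, 3] - 1) * bd[1] * bd[2] + (ix[, 2] - 1) * bd[1] + ix[, 1]
  fg <- unique(lin(line_idx))
  bg <- unique(lin(ring_idx))
  if (length(intersect(fg, bg))) {
    stopf("foreground line and background ring seeds overlap (ring_factor too small)")
  }

  # sigma from seed-neighbourhood gradients (one-voxel dilated seed set).
  # Robust (MAD) estimate: the neighbourhood of the line's endpoints
  # touches the lesion boundary, and a non-robust sd would be inflated
  # by those boundary steps, cheapening boundary edges until the cut
  # collapses onto the line seeds (shrinking bias).
  seed_mask <- array(FALSE, bd)
  seed_mask[c(fg, bg)] <- TRUE
  seed_nb <- dilate_mask_mm(seed_mask, max(vol$spacing) + 1e-6, vol$spacing)
  grads <- c(
    diff_axis(sub, 1)[diff_axis(seed_nb, 1, op = "&")],
    diff_axis(sub, 2)[diff_axis(seed_nb, 2, op = "&")],
    diff_axis(sub, 3)[diff_axis(seed_nb, 3, op = "&")]
  )
  sigma <- stats::mad(grads)
  degenerate <- !is.finite(sigma) || sigma < 1e-8
  if (degenerate) sigma <- 1

  n <- prod(bd)
  edges <- NULL
  caps <- NULL
  for (ax in 1:3) {
    dI <- diff_axis(sub, ax)
    # linear indices of the lower voxel of each pair along `ax`; which()
    # enumerates in the same column-major order as as.numeric(dI)
    idxs <- which(slice_head(array(TRUE, bd), ax))
    w <- exp(-(as.numeric(dI)^2) / (2 * sigma^2))
    step <- c(1, bd[1], bd[1] * bd[2])[ax]
    sel <- w > cap_epsilon
    edges <- rbind(edges, cbind(idxs[sel], idxs[sel] + step))
    caps <- c(caps, w[sel])
  }
  src <- n + 1L
  snk <- n + 2L
  big <- sum(caps) + 1
  edges <- rbind(edges, cbind(src, fg), cbind(snk, bg))
  caps <- c(caps, rep(big, length(fg)), rep(big, length(bg)))
  g <- igraph::make_graph(t(edges), n = n + 2L, directed = FALSE)
  flow <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  part <- as.integer(flow$partition1)
  if (!(src %in% part)) part <- as.integer(flow$partition2)
  fg_mask <- array(FALSE, bd)
  fg_mask[part[part <= n]] <- TRUE

  # keep only the 6-connected component containing the line seeds
  comp <- connected_component(fg_mask, fg)
  out <- array(FALSE, d)
  out[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1] <- comp
  out <- out & lung$mask
  if (!any(out)) stopf("solid segmentation is empty after lung intersection")
  res <- roi_mask(out, vol, "solid", sub_label = "solid")
  attr(res, "degenerate") <- degenerate
  res
}

# forward difference (numeric) or pairwise conjunction (logical) along an axis
diff_axis <- function(arr, ax, op = "-") {
  d <- dim(arr)
  idx_lo <- lapply(seq_along(d), function(i) if (i == ax) seq_len(d[i] - 1) else seq_len(d[i]))
  idx_hi <- lapply(seq_along(d), function(i) if (i == ax) 1 + seq_len(d[i] - 1) else seq_len(d[i]))
  a <- do.call(`[`, c(list(arr), idx_lo, list(drop = FALSE)))
  b <- do.call(`[`, c(list(arr), idx_hi, list(drop = FALSE)))
  if (op == "&") a & b else b - a
}

# mask of the "lower" voxel of each along-axis neighbour pair
slice_head <- function(arr, ax) {
  d <- dim(arr)
  out <- array(FALSE, d)
  idx <- lapply(seq_along(d), function(i) if (i == ax) seq_len(d[i] - 1) else seq_len(d[i]))
  out_idx <- do.call(`[<-`, c(list(out), idx, list(value = TRUE)))
  out_idx
}

# 6-connected component of `mask` containing any of the seed linear indices
connected_component <- function(mask, seeds) {
  d <- dim(mask)
  step <- c(1L, d[1], d[1] * d[2])
  lab <- array(FALSE, d)
  frontier <- intersect(seeds, which(mask))
  lab[frontier] <- TRUE
  nvox <- prod(d)
  ii <- function(lin) ((lin - 1L) %% d[1]) + 1L
  jj <- function(lin) (((lin - 1L) %/% d[1]) %% d[2]) + 1L
  kk <- function(lin) ((lin - 1L) %/% (d[1] * d[2])) + 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in 1:3) {
      ok_up <- switch(s, ii(frontier) < d[1], jj(frontier) < d[2], kk(frontier) < d[3])
      ok_dn <- switch(s, ii(frontier) > 1L, jj(frontier) > 1L, kk(frontier) > 1L)
      nxt <- c(nxt, frontier[ok_up] + step[s], frontier[ok_dn] - step[s])
    }
    nxt <- unique(nxt)
    nxt <- nxt[nxt >= 1 & nxt <= nvox]
    nxt <- nxt[mask[nxt] & !lab[nxt]]
    lab[nxt] <- TRUE
    frontier <- nxt
  }
  lab
}

#' Ground-glass-opacity sub-ROI: concentric mm expansion of the solid
#'
#' All voxels whose center lies within `width` mm (anisotropic
#' world-space Euclidean distance) of any solid voxel center, excluding
#' the solid itself, intersected with the lung.
#'
#' @param solid the solid `roi_mask` from [segment_solid()].
#' @param width expansion width in mm (default 16).
#' @param lung the lung `roi_mask`.
#' @return A `roi_mask` of kind `"ggo"`.
#' @export
expand_ggo <- function(solid, width = 16, lung) {
  stopifnot(inherits(solid, "roi_mask"), inherits(lung, "roi_mask"))
  if (!any(solid$mask)) stopf("solid mask is empty")
  if (width <= 0) stopf("`width` must be > 0")
  dil <- dilate_mask_mm(solid$mask, width, solid$spacing)
  out <- dil & !solid$mask & lung$mask
  if (!any(out)) stopf("GGO expansion is empty after lung intersection")
  roi_mask(out, solid, "ggo", sub_label = "ggo")
}

#' Build all six ROI masks for one case
#'
#' @inheritParams build_sphere
#' @param cylinder_radius mm (default 10).
#' @param ggo_expansion mm (default 16).
#' @param ring_factor background-ring factor for [segment_solid()].
#' @return Named list over `lung_slice`, `solid_ggo`, `cylinder`,
#'   `sphere20`, `sphere40`, `sphere_recist`; the `solid_ggo` entry is
#'   itself a list with `solid` and `ggo` sub-masks.
#' @export
build_all_rois <- function(a, vol, lung, cylinder_radius = 10, ggo_expansion = 16,
                           ring_factor = 1.5) {
  wrap <- function(kind, expr) {
    tryCatch(expr, error = function(e) {
      stopf("ROI '%s' failed: %s", kind, conditionMessage(e))
    })
  }
  solid <- wrap("solid_ggo", segment_solid(a, vol, lung, ring_factor = ring_factor))
  list(
    lung_slice = wrap("lung_slice", build_lung_slice(a, vol, lung)),
    solid_ggo = list(
      solid = solid,
      ggo = wrap("solid_ggo", expand_ggo(solid, ggo_expansion, lung))
    ),
    cylinder = wrap("cylinder", build_cylinder(a, cylinder_radius, vol, lung)),
    sphere20 = wrap("sphere20", build_sphere(a, 20, vol, lung)),
    sphere40 = wrap("sphere40", build_sphere(a, 40, vol, lung)),
    sphere_recist = wrap("sphere_recist", build_sphere(a, recist_length(a), vol, lung))
  )
}
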