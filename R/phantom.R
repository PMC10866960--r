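#' Parameters for the synthetic post-SABR CT cohort
#'
#' The phantom emulates the statistical structure the downstream analysis
#' assumes: anisotropic CT voxels, a lung field with parenchyma/lesion HU
#' contrast, one lesion per case whose longest axial diameter averages
#' ~55 mm, serial RECIST measurements that trigger progressive disease,
#' and two outcome classes (recurrence vs RILI) that differ in lesion
#' density and texture. Class contrasts are encoded as the lesion mean HU,
#' the intensity spread, and the spatial correlation length of the
#' texture: recurrent lesions are denser, tighter and smoother, so their
#' within-ROI mean is higher, their skewness lower and their GLCM
#' maximum/joint energy higher, matching the direction (not the effect
#' size, which the source cohort does not expose) of the planted effects
#' the experiments recover.
#'
#' @param n_cases number of patients.
#' @param prevalence fraction of recurrence cases in `[0, 1]`; assignment
#'   is stratified so exactly `round(prevalence * n_cases)` cases are
#'   labelled recurrence.
#' @param voxel_spacing default voxel size in mm (in-plane x, in-plane y,
#'   slice thickness).
#' @param grid_shape grid dimensions in voxels at the default spacing.
#' @param lung_hu_mean,lung_hu_sd lung parenchyma intensity model (HU).
#' @param lesion_hu_mean_by_class named HU means, names exactly
#'   `recurrence` and `rili`.
#' @param lesion_hu_sd_by_class named within-lesion HU standard
#'   deviations (texture amplitude).
#' @param lesion_hu_between_sd between-case standard deviation (HU) of
#'   the lesion mean around its class value; without it every case of a
#'   class would have an identical within-lesion mean, which no real
#'   cohort shows.
#' @param lesion_hu_sd_between between-case standard deviation (HU) of
#'   the within-lesion texture amplitude around its class value.
#' @param lesion_texture_corr_len_cv between-case lognormal coefficient
#'   of variation of the texture correlation length. Together with
#'   `lesion_hu_sd_between` this makes the class-conditional lesion
#'   appearance distributions overlap, as they do clinically; with
#'   point-mass class conditionals the two outcomes would be trivially
#'   separable.
#' @param lesion_texture_corr_len_by_class named Gaussian correlation
#'   lengths in mm of the within-lesion texture (smoothed white noise).
#' @param lesion_diameter_mean,lesion_diameter_sd longest-axial-diameter
#'   distribution (mm) of the lesion on the progressive-disease scan;
#'   draws are clipped to `[25, 70]` mm so lesion plus halo stay inside
#'   the lung field.
#' @param ggo_halo_width width (mm) of the intermediate-density halo
#'   surrounding the lesion, emulating ground-glass opacification.
#' @param n_followups number of follow-up scans after baseline.
#' @param growth_schedule_by_class named list of per-scan multiplicative
#'   size factors (length `n_followups + 1`, entry 1 = baseline). The
#'   RILI schedule shrinks then regrows past the progressive-disease
#'   thresholds (pseudo-progression); the recurrence schedule grows
#'   monotonically. Both trigger PD at the final scan by design.
#' @param randomize_spacing draw per-case spacing from the scanner ranges
#'   (in-plane 0.57-0.84 mm, slice 1.5-5.0 mm) instead of the fixed
#'   default, so the resampling stage is exercised.
#' @param seed integer RNG seed; identical parameters give a
#'   bit-identical cohort.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_cases = 68L,
                           prevalence = 0.41,
                           voxel_spacing = c(0.74, 0.74, 5.0),
                           grid_shape = c(128L, 128L, 28L),
                           lung_hu_mean = -850,
                           lung_hu_sd = 40,
                           lesion_hu_mean_by_class = c(recurrence = -60, rili = -100),
                           lesion_hu_sd_by_class = c(recurrence = 100, rili = 112),
                           lesion_hu_between_sd = 35,
                           lesion_hu_sd_between = 35,
                           lesion_texture_corr_len_by_class = c(recurrence = 2.3, rili = 1.65),
                           lesion_texture_corr_len_cv = 0.8,
                           lesion_diameter_mean = 55,
                           lesion_diameter_sd = 10,
                           ggo_halo_width = 8,
                           n_followups = 3L,
                           growth_schedule_by_class = list(
                             recurrence = c(1.00, 1.06, 1.14, 1.32),
                             rili = c(1.00, 0.60, 0.66, 0.85)
                           ),
                           randomize_spacing = FALSE,
                           seed = 1L) {
  chk_class_named <- function(x, nm) {
    if (!setequal(names(x), c("recurrence", "rili"))) {
      stopf("`%s` must be named with exactly {recurrence, rili}", nm)
    }
  }
  if (!is.numeric(n_cases) || n_cases < 1) stopf("`n_cases` must be a positive count")
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    stopf("`prevalence` must be in [0, 1]")
  }
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stopf("`voxel_spacing` must be 3 positive values (mm)")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 8)) {
    stopf("`grid_shape` must be 3 counts >= 8")
  }
  if (lesion_diameter_sd < 0) stopf("`lesion_diameter_sd` must be >= 0")
  if (ggo_halo_width < 0) stopf("`ggo_halo_width` must be >= 0")
  if (n_followups < 1) stopf("`n_followups` must be >= 1")
  chk_class_named(lesion_hu_mean_by_class, "lesion_hu_mean_by_class")
  chk_class_named(lesion_hu_sd_by_class, "lesion_hu_sd_by_class")
  if (lesion_hu_between_sd < 0) stopf("`lesion_hu_between_sd` must be >= 0")
  if (lesion_hu_sd_between < 0) stopf("`lesion_hu_sd_between` must be >= 0")
  if (lesion_texture_corr_len_cv < 0) stopf("`lesion_texture_corr_len_cv` must be >= 0")
  chk_class_named(lesion_texture_corr_len_by_class, "lesion_texture_corr_len_by_class")
  chk_class_named(growth_schedule_by_class, "growth_schedule_by_class")
  for (cl in c("recurrence", "rili")) {
    sched <- growth_schedule_by_class[[cl]]
    if (length(sched) != n_followups + 1L || any(sched <= 0)) {
      stopf("`growth_schedule_by_class$%s` must be %d positive factors", cl, n_followups + 1L)
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases), prevalence = prevalence,
      voxel_spacing = as.numeric(voxel_spacing),
      grid_shape = as.integer(grid_shape),
      lung_hu_mean = lung_hu_mean, lung_hu_sd = lung_hu_sd,
      lesion_hu_mean_by_class = lesion_hu_mean_by_class,
      lesion_hu_sd_by_class = lesion_hu_sd_by_class,
      lesion_hu_between_sd = lesion_hu_between_sd,
      lesion_hu_sd_between = lesion_hu_sd_between,
      lesion_texture_corr_len_cv = lesion_texture_corr_len_cv,
      lesion_texture_corr_len_by_class = lesion_texture_corr_len_by_class,
      lesion_diameter_mean = lesion_diameter_mean,
      lesion_diameter_sd = lesion_diameter_sd,
      ggo_halo_width = ggo_halo_width,
      n_followups = as.integer(n_followups),
      growth_schedule_by_class = growth_schedule_by_class,
      randomize_spacing = isTRUE(randomize_spacing),
      seed = as.integer(seed)
    ),
    class = "phantom_params"
  )
}

# voxel-center mask of an axis-aligned ellipsoid, on the grid of `geom`
ellipsoid_mask <- function(geom, center, semi) {
  mx <- ((axis_coords(geom, 1) - center[1]) / semi[1])^2
  my <- ((axis_coords(geom, 2) - center[2]) / semi[2])^2
  mz <- ((axis_coords(geom, 3) - center[3]) / semi[3])^2
  outer(outer(mx, my, "+"), mz, "+") <= 1
}

#' Synthesize one irregular lesion with spatially correlated texture
#'
#' The lesion is a union of 2-4 overlapping axis-aligned ellipsoids
#' (irregular margins without anatomical modelling), rescaled once so the
#' longest axial diameter of the voxelized mask matches `diameter` to
#' within voxel quantization. Intensities are smoothed white noise:
#' Gaussian-filtered iid noise with per-axis kernel sd equal to
#' `texture_corr_len` mm, re-standardised to `hu_mean` / `hu_sd` over the
#' lesion voxels. `texture_corr_len = 0` gives voxelwise-independent
#' noise.
#'
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param center lesion center, mm world coordinates.
#' @param diameter target longest axial diameter, mm (> 0).
#' @param texture_corr_len texture correlation length, mm.
#' @param hu_mean,hu_sd lesion intensity mean and sd (HU).
#' @param dim,spacing,origin grid geometry the lesion is rasterised on.
#' @return list with `mask` (logical array), `hu` (numeric array, NA
#'   outside the lesion) and `ellipsoids` (list of center/semi pairs, mm).
#' @export
synthesize_lesion <- function(center, diameter, texture_corr_len, hu_mean, hu_sd,
                              dim, spacing, origin = c(0, 0, 0)) {
  if (diameter <= 0) stopf("`diameter` must be > 0")
  geom <- list(mask = array(FALSE, dim), spacing = spacing, origin = origin)
  vol_geom <- image_volume(array(0, dim), spacing, origin)

  if (diameter < min(spacing[1:2])) {
    # sub-voxel lesion: the single voxel containing the center
    idx <- round(world_to_voxel(vol_geom, center))
    if (any(idx < 0) || any(idx > dim - 1)) stopf("lesion extends beyond the grid")
    mask <- array(FALSE, dim)
    mask[idx[1] + 1, idx[2] + 1, idx[3] + 1] <- TRUE
    hu <- array(NA_real_, dim)
    hu[mask] <- stats::rnorm(1, hu_mean, hu_sd)
    return(list(mask = mask, hu = hu, ellipsoids = list()))
  }

  n_lobes <- sample(2:4, 1)
  r <- diameter / 2
  prim_semi <- r * c(1, stats::runif(1, 0.75, 1), stats::runif(1, 0.6, 0.9))
  ell <- list(list(center = center, semi = prim_semi))
  for (i in seq_len(n_lobes - 1L)) {
    off <- stats::runif(3, -0.4, 0.4) * prim_semi
    semi <- prim_semi * stats::runif(3, 0.35, 0.6)
    ell[[i + 1L]] <- list(center = center + off, semi = semi)
  }
  build <- function(scale) {
    m <- array(FALSE, dim)
    for (e in ell) {
      cen <- center + (e$center - center) * scale
      m <- m | ellipsoid_mask(vol_geom, cen, pmax(e$semi * scale, min(spacing) / 2))
    }
    m
  }
  mask <- build(1)
  if (!any(mask)) stopf("lesion extends beyond the grid or is sub-voxel")
  # one rescale pass so the measured axial diameter hits the request
  L0 <- recist_length(derive_recist_line(roi_mask(mask, vol_geom, "lesion")))
  if (L0 > 0) {
    scale <- diameter / L0
    mask <- build(scale)
    for (i in seq_along(ell)) {
      ell[[i]]$center <- center + (ell[[i]]$center - center) * scale
      ell[[i]]$semi <- ell[[i]]$semi * scale
    }
  }
  d <- dim
  edge <- any(mask[1, , ]) || any(mask[d[1], , ]) || any(mask[, 1, ]) ||
    any(mask[, d[2], ]) || any(mask[, , 1]) || any(mask[, , d[3]])
  if (edge) stopf("lesion extends beyond the grid")

  # correlated texture on the lesion bounding box
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  box <- hi - lo + 1L
  noise <- array(stats::rnorm(prod(box)), dim = box)
  sigma_vox <- texture_corr_len / spacing
  noise <- smooth_gaussian(noise, sigma_vox)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  v <- noise[sub]
  v <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  hu <- array(NA_real_, dim)
  hu[mask] <- hu_mean + hu_sd * v
  list(mask = mask, hu = hu, ellipsoids = ell)
}

# lung field: a single smooth ellipsoid centered in the grid (a deliberate
# simplification -- no airways, vessels or fibrosis; see the vignette)
lung_geometry <- function(dim, spacing, origin) {
  extent <- dim * spacing
  list(
    center = origin + (dim - 1) * spacing / 2,
    semi = c(0.42, 0.42, 0.45) * extent
  )
}

#' Rebuild a phantom case's lung mask on an arbitrary grid
#'
#' ROI masks are never interpolated in this package; after resampling a
#' volume, masks are re-derived from mm-space geometry. The phantom
#' stores its analytic lung ellipsoid so this is exact.
#'
#' @param case a `phantom_case`.
#' @param vol the (possibly resampled) [image_volume()] to build on.
#' @return A `roi_mask` of kind `"lung"`.
#' @export
lung_mask_on_grid <- function(case, vol) {
  roi_mask(ellipsoid_mask(vol, case$lung_center, case$lung_semi), vol, "lung")
}

#' Generate a synthetic cohort of post-SABR progressive-disease cases
#'
#' Each case carries the CT volume of the progressive-disease (PD) scan,
#' the lung mask, the ground-truth lesion mask, the serial RECIST
#' measurements (with full line geometry on every scan, scaled versions
#' of the PD-scan line), the outcome label, and the PD scan index as
#' found by [find_pd_scan()].
#'
#' @param params a [phantom_params()].
#' @return list of `phantom_case` objects, length `n_cases`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$n_cases
  set.seed(params$seed)
  n_pos <- round(params$prevalence * n)
  labels <- sample(c(rep("recurrence", n_pos), rep("rili", n - n_pos)))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    make_phantom_case(i, labels[i], case_seeds[i], params)
  })
}

make_phantom_case <- function(case_id, label, case_seed, params) {
  set.seed(case_seed)
  extent <- params$grid_shape * params$voxel_spacing
  if (params$randomize_spacing) {
    sp_xy <- stats::runif(1, 0.57, 0.84)
    spacing <- c(sp_xy, sp_xy, stats::runif(1, 1.5, 5.0))
    dim <- pmax(8L, as.integer(round(extent / spacing)))
  } else {
    spacing <- params$voxel_spacing
    dim <- params$grid_shape
  }
  origin <- c(0, 0, 0)
  lung <- lung_geometry(dim, spacing, origin)

  vol_geom <- image_volume(array(0, dim), spacing, origin)
  lung_mask_arr <- ellipsoid_mask(vol_geom, lung$center, lung$semi)
  nvox <- prod(dim)
  data <- array(20 + stats::rnorm(nvox, 0, 15), dim)  # soft-tissue background
  data[lung_mask_arr] <- params$lung_hu_mean +
    stats::rnorm(sum(lung_mask_arr), 0, params$lung_hu_sd)

  diam <- min(70, max(25, stats::rnorm(1, params$lesion_diameter_mean,
                                       params$lesion_diameter_sd)))
  center <- lung$center + c(stats::runif(2, -3, 3), stats::runif(1, -2.5, 2.5))
  # per-case draws around the class-conditional appearance parameters
  cv <- params$lesion_texture_corr_len_cv
  corr_len <- params$lesion_texture_corr_len_by_class[[label]]
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    corr_len <- stats::rlnorm(1, log(corr_len) - sdlog^2 / 2, sdlog)
  }
  hu_sd_case <- max(20, params$lesion_hu_sd_by_class[[label]] +
                      stats::rnorm(1, 0, params$lesion_hu_sd_between))
  les <- synthesize_lesion(
    center, diam, corr_len,
    params$lesion_hu_mean_by_class[[label]] +
      stats::rnorm(1, 0, params$lesion_hu_between_sd),
    hu_sd_case,
    dim, spacing, origin
  )
  lesion_arr <- les$mask & lung_mask_arr

  # ground-glass-like halo: inflated copies of the lesion ellipsoids
  if (params$ggo_halo_width > 0 && length(les$ellipsoids)) {
    halo <- array(FALSE, dim)
    for (e in les$ellipsoids) {
      halo <- halo | ellipsoid_mask(vol_geom, e$center, e$semi + params$ggo_halo_width)
    }
    halo <- halo & lung_mask_arr & !lesion_arr
    halo_mean <- (params$lesion_hu_mean_by_class[[label]] + params$lung_hu_mean) / 2
    data[halo] <- halo_mean + stats::rnorm(sum(halo), 0, 100)
  }
  data[lesion_arr] <- les$hu[lesion_arr]

  vol <- image_volume(data, spacing, origin)
  lung_mask <- roi_mask(lung_mask_arr, vol, "lung")
  lesion_mask <- roi_mask(lesion_arr, vol, "lesion")

  a_pd <- derive_recist_line(lesion_mask)
  L <- recist_length(a_pd)
  sched <- params$growth_schedule_by_class[[label]]
  n_scans <- length(sched)
  lengths <- L * sched / sched[n_scans] * stats::runif(n_scans, 0.99, 1.01)
  pd_idx <- find_pd_scan(lengths)
  for (k in 1:3) {
    if (is.na(pd_idx) || abs(lengths[pd_idx] - L) < 1e-9) break
    lengths <- lengths * (L / lengths[pd_idx])
    pd_idx <- find_pd_scan(lengths)
  }
  if (is.na(pd_idx)) {
    stopf("growth schedule for case %d (%s) never triggers progressive disease", case_id, label)
  }
  u <- (a_pd$p2 - a_pd$p1) / max(L, 1e-9)
  M <- recist_midpoint(a_pd)
  series <- lapply(seq_len(n_scans), function(t) {
    recist_annotation(M - u * lengths[t] / 2, M + u * lengths[t] / 2,
                      a_pd$slice_index, scan_index = t)
  })

  structure(
    list(
      case_id = case_id, label = label,
      volume = vol, lung_mask = lung_mask, lesion_mask_truth = lesion_mask,
      recist_series = series, lengths_mm = lengths,
      pd_scan_index = pd_idx, recist_pd = series[[pd_idx]],
      lung_center = lung$center, lung_semi = lung$semi,
      seed = case_seed
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case> #%d [%s], lesion %.1f mm, PD at scan %s of %d\n",
    x$case_id, x$label, recist_length(x$recist_pd),
    ifelse(is.na(x$pd_scan_index), "none", x$pd_scan_index),
    length(x$recist_series)
  ))
  invisible(x)
}

#' Write a cohort's annotation table and (optionally) its volumes
#'
#' The annotation table is the canonical exchange format: one row per
#' case and scan with world-coordinate RECIST endpoints, length, and the
#' outcome label.
#'
#' @param cohort list of `phantom_case` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param write_volumes also write each PD-scan volume, lung mask and
#'   lesion truth mask as NIfTI.
#' @return path of the annotation CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_volumes = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(cohort, function(cs) {
    do.call(rbind, lapply(cs$recist_series, function(a) {
      data.frame(
        case_id = cs$case_id, scan_index = a$scan_index,
        x1 = a$p1[1], y1 = a$p1[2], z = a$p1[3], x2 = a$p2[1], y2 = a$p2[2],
        length_mm = a$length_mm,
        pd_scan = cs$pd_scan_index, label = cs$label
      )
    }))
  }))
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  if (write_volumes) {
    for (cs in cohort) {
      stub <- file.path(dir, sprintf("case%03d", cs$case_id))
      write_volume(cs$volume, paste0(stub, "_ct.nii.gz"))
      write_volume(cs$lung_mask, paste0(stub, "_lung.nii.gz"))
      write_volume(cs$lesion_mask_truth, paste0(stub, "_lesion.nii.gz"))
    }
  }
  invisible(csv)
}
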