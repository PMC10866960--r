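#' In-memory CT volume with world-space geometry
#'
#' A 3D scalar grid of Hounsfield units together with per-axis voxel
#' spacing (mm) and the world position of the center of voxel (0,0,0).
#' Axis order is fixed as (x, y, z) with z the slice axis, and all
#' geometric computations in the package are done in mm world space with
#' 0-based voxel indices addressing voxel centers.
#'
#' @param data 3D numeric array of intensities (HU); must be finite.
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, world coordinates (mm) of the center of
#'   the first voxel.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("`data` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be 3 strictly positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stopf("`origin` must be 3 finite values (mm)")
  }
  if (any(!is.finite(data))) stopf("`data` must be finite")
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, origin (%.3g, %.3g, %.3g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Boolean region-of-interest mask aligned to a volume grid
#'
#' @param mask 3D logical array, same grid as the parent volume.
#' @param vol the parent [image_volume()] supplying the geometry.
#' @param kind one of `"lung"`, `"lung_slice"`, `"solid"`, `"ggo"`,
#'   `"cylinder"`, `"sphere20"`, `"sphere40"`, `"sphere_recist"`, or
#'   `"lesion"` (phantom ground truth).
#' @param sub_label optional sub-ROI tag (e.g. `"solid"`/`"ggo"`).
#' @param two_d flag a single-slice (2D) ROI so shape features are skipped.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, vol, kind, sub_label = NULL, two_d = FALSE) {
  kinds <- c(
    "lung", "lung_slice", "solid", "ggo", "cylinder",
    "sphere20", "sphere40", "sphere_recist", "lesion"
  )
  kind <- match.arg(kind, kinds)
  ref_dim <- dim(vol$data %||% vol$mask)
  if (!is.logical(mask) || !identical(dim(mask), ref_dim)) {
    stopf("`mask` must be a logical array on the same grid as `vol`")
  }
  structure(
    list(
      mask = mask, spacing = vol$spacing, origin = vol$origin,
      kind = kind, sub_label = sub_label, two_d = isTRUE(two_d)
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> kind=%s%s, %d voxels%s\n", x$kind,
    if (!is.null(x$sub_label)) paste0("/", x$sub_label) else "",
    sum(x$mask), if (x$two_d) " (2D)" else ""
  ))
  invisible(x)
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' Uses the voxel-center convention: index i maps to
#' `origin + i * spacing`, so `world_to_voxel` and [voxel_to_world()] are
#' mutually inverse.
#'
#' @param vol an [image_volume()] (or `roi_mask`, which carries geometry).
#' @param points numeric length-3 vector or n x 3 matrix of mm coordinates.
#' @return Continuous 0-based indices, same shape as the input.
#' @export
world_to_voxel <- function(vol, points) {
  if (is.null(dim(points))) {
    (as.numeric(points) - vol$origin) / vol$spacing
  } else {
    sweep(sweep(points, 2, vol$origin, "-"), 2, vol$spacing, "/")
  }
}

#' Convert 0-based voxel indices to world coordinates (mm)
#' @inheritParams world_to_voxel
#' @param index numeric length-3 vector or n x 3 matrix of 0-based indices
#'   (fractional indices are allowed).
#' @export
voxel_to_world <- function(vol, index) {
  if (is.null(dim(index))) {
    vol$origin + as.numeric(index) * vol$spacing
  } else {
    sweep(sweep(index, 2, vol$spacing, "*"), 2, vol$origin, "+")
  }
}

# world-space voxel center coordinates along one axis
axis_coords <- function(vol, ax) {
  n <- dim(vol$data %||% vol$mask)[ax]
  vol$origin[ax] + (seq_len(n) - 1) * vol$spacing[ax]
}

#' Read a volume from NIfTI (.nii/.nii.gz) or MetaImage (.mha/.mhd)
#'
#' Only axis-aligned (RAS-like) orientations are supported; oblique
#' orientation matrices are rejected, as is non-positive spacing.
#'
#' @param path file path; the format is chosen by extension.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_volume_nifti(path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_volume_meta(path)
  } else {
    stopf("unsupported volume format: %s (use .nii, .nii.gz, .mha or .mhd)", path)
  }
}

#' Write a volume to NIfTI or MetaImage
#'
#' Round-trips intensities, spacing and origin. `.mhd` writes the raw
#' block to a sibling `.raw` file; `.mha` embeds it.
#'
#' @param vol an [image_volume()].
#' @param path destination path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume") || inherits(vol, "roi_mask"))
  if (inherits(vol, "roi_mask")) {
    vol <- image_volume(
      array(as.numeric(vol$mask), dim(vol$mask)), vol$spacing, vol$origin
    )
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_volume_nifti(vol, path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_volume_meta(vol, path)
  } else {
    stopf("unsupported volume format: %s", path)
  }
  invisible(path)
}

read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  m <- RNifti::xform(im)
  rot <- m[1:3, 1:3]
  if (max(abs(rot[upper.tri(rot) | lower.tri(rot)])) > 1e-6 * max(abs(diag(rot)))) {
    stopf("oblique orientation in %s is not supported", path)
  }
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) stopf("non-positive voxel spacing in %s", path)
  if (any(diag(rot) < 0)) stopf("axis-flipping orientation in %s is not supported", path)
  origin <- m[1:3, 4]
  arr <- array(as.numeric(im), dim = dim(im)[1:3])
  image_volume(arr, spacing, origin)
}

write_volume_nifti <- function(vol, path) {
  im <- RNifti::asNifti(vol$data)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  im <- RNifti::`qform<-`(im, structure(m, code = 2L))
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
}

# Minimal MetaImage (ITK MET_*) support: uncompressed, axis-aligned,
# little-endian. Header fields beyond the ones below are ignored.
read_volume_meta <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stopf("unexpected end of header in %s", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stopf("MetaImage header missing %s in %s", paste(miss, collapse = ", "), path)
  if (as.integer(hdr$NDims) != 3L) stopf("only 3D MetaImage supported")
  if (identical(hdr[["CompressedData"]], "True")) stopf("compressed MetaImage not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  if (any(spacing <= 0)) stopf("non-positive voxel spacing in %s", path)
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  tm <- hdr[["TransformMatrix"]]
  if (!is.null(tm)) {
    tm <- as.numeric(strsplit(tm, "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6) {
      stopf("oblique orientation in %s is not supported", path)
    }
  }
  type <- hdr$ElementType
  spec <- switch(type,
    MET_DOUBLE = list(what = "numeric", size = 8L),
    MET_FLOAT = list(what = "numeric", size = 4L),
    MET_SHORT = list(what = "integer", size = 2L),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR = list(what = "integer", size = 1L),
    stopf("unsupported MetaImage ElementType: %s", type)
  )
  n <- prod(d)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, spec$what, n = n, size = spec$size,
                   signed = spec$signed %||% TRUE, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stopf("MetaImage data file not found: %s", raw_path)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, spec$what, n = n, size = spec$size,
                   signed = spec$signed %||% TRUE, endian = "little")
  }
  if (length(raw) != n) stopf("truncated MetaImage data in %s", path)
  image_volume(array(as.numeric(raw), dim = d), spacing, origin)
}

write_volume_meta <- function(vol, path) {
  d <- dim(vol$data)
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  data_file <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE",
    paste0("ElementDataFile = ", data_file)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(vol$data), rcon, size = 8L, endian = "little")
  }
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation on intensities. The output grid preserves the
#' world-space extent to within one output voxel: the number of output
#' voxels per axis is `round(n_in * spacing_in / spacing_out)` and the
#' grid corner (edge of the first voxel) is kept fixed, so
#' `origin_out = origin_in + (spacing_out - spacing_in) / 2`.
#' Output voxel centers falling outside the source center range are
#' clamped to the nearest source voxel (edge replication). ROI masks are
#' never interpolated; rebuild them on the resampled grid from mm-space
#' geometry instead.
#'
#' @param vol an [image_volume()].
#' @param target_spacing numeric length-3 (mm), strictly positive.
#' @return A resampled [image_volume()] with `spacing == target_spacing`.
#' @export
resample <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "image_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0)) {
    stopf("`target_spacing` must be 3 strictly positive values (mm)")
  }
  d_in <- dim(vol$data)
  if (any(d_in == 1L)) stopf("cannot resample a degenerate (single-voxel) axis")
  n_out <- pmax(1L, as.integer(round(d_in * vol$spacing / target_spacing)))
  origin_out <- vol$origin + (target_spacing - vol$spacing) / 2
  arr <- vol$data
  for (ax in 1:3) {
    # world coords of output centers along this axis, as continuous source index
    w <- origin_out[ax] + (seq_len(n_out[ax]) - 1) * target_spacing[ax]
    t <- (w - vol$origin[ax]) / vol$spacing[ax]
    t <- pmin(pmax(t, 0), d_in[ax] - 1)
    i0 <- pmin(floor(t), d_in[ax] - 2)
    f <- t - i0
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    da <- dim(arr)
    m <- matrix(arr, nrow = da[1])
    m_out <- m[i0 + 1L, , drop = FALSE] * (1 - f) + m[i0 + 2L, , drop = FALSE] * f
    arr <- array(m_out, dim = c(n_out[ax], da[2], da[3]))
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  image_volume(arr, target_spacing, origin_out)
}
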