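#' RECIST line annotation
#'
#' The longest axial diameter of a lesion as drawn by a clinician on a
#' single axial CT slice: two endpoints in world coordinates (mm) sharing
#' the same z, plus the slice index and the temporal scan index.
#'
#' @param p1,p2 numeric length-3 endpoints in mm; `p1[3]` must equal
#'   `p2[3]` (same axial slice).
#' @param slice_index 0-based voxel slice index of the line.
#' @param scan_index temporal order of the scan (1 = pre-treatment
#'   baseline).
#' @return An object of class `recist_annotation` with the derived field
#'   `length_mm`.
#' @export
recist_annotation <- function(p1, p2, slice_index, scan_index = NA_integer_) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 3L || length(p2) != 3L) stopf("endpoints must be mm 3-vectors")
  if (abs(p1[3] - p2[3]) > 1e-6) {
    stopf("RECIST endpoints must lie on the same axial slice (z %.6g != %.6g)", p1[3], p2[3])
  }
  structure(
    list(
      p1 = p1, p2 = p2,
      slice_index = as.integer(slice_index),
      scan_index = as.integer(scan_index),
      length_mm = sqrt(sum((p1 - p2)^2))
    ),
    class = "recist_annotation"
  )
}

#' @export
print.recist_annotation <- function(x, ...) {
  cat(sprintf(
    "<recist_annotation> %.1f mm on slice %d (scan %s)\n",
    x$length_mm, x$slice_index,
    if (is.na(x$scan_index)) "?" else x$scan_index
  ))
  invisible(x)
}

#' Length of a RECIST line in mm
#'
#' Euclidean in-plane distance between the two endpoints.
#'
#' @param a a [recist_annotation()].
#' @return length in mm.
#' @export
recist_length <- function(a) {
  stopifnot(inherits(a, "recist_annotation"))
  a$length_mm
}

#' Midpoint of a RECIST line (mm world coordinates)
#' @inheritParams recist_length
#' @export
recist_midpoint <- function(a) {
  stopifnot(inherits(a, "recist_annotation"))
  (a$p1 + a$p2) / 2
}

#' Serial RECIST length measurements for one lesion
#'
#' @param lengths ordered numeric vector of RECIST line lengths in mm;
#'   entry 1 is the pre-treatment baseline. At least 2 entries, all
#'   strictly positive.
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) stopf("a measurement series needs at least 2 scans")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stopf("all RECIST lengths must be strictly positive")
  }
  structure(list(lengths = lengths), class = "measurement_series")
}

#' First scan triggering RECIST 1.1 progressive disease
#'
#' Progressive disease (PD) for a single lesion: an increase of >= 20% in
#' the longest axial diameter relative to its smallest size so far (the
#' nadir, i.e. the running minimum over all earlier scans *including* the
#' pre-treatment baseline and the current scan), that is also >= 5 mm in
#' absolute terms. Returns the earliest follow-up scan at which both
#' criteria hold. Exact ties (exactly 20% / exactly 5 mm) count as PD;
#' comparisons carry a 1e-9 relative tolerance so ties are not lost to
#' floating point.
#'
#' @param s a [measurement_series()] or a plain numeric vector of lengths.
#' @return 1-based index of the PD scan (always >= 2), or `NA_integer_`
#'   if PD is never triggered.
#' @export
find_pd_scan <- function(s) {
  if (inherits(s, "measurement_series")) s <- s$lengths
  s <- as.numeric(s)
  if (length(s) < 2L) stopf("a measurement series needs at least 2 scans")
  if (any(!is.finite(s)) || any(s <= 0)) stopf("all RECIST lengths must be strictly positive")
  run_min <- cummin(s)
  for (t in 2:length(s)) {
    nadir <- run_min[t]
    tol <- 1e-9 * max(1, nadir)
    if (s[t] >= 1.2 * nadir - tol && (s[t] - nadir) >= 5 - tol) {
      return(t)
    }
  }
  NA_integer_
}

#' Derive the RECIST line from a lesion mask
#'
#' Finds, within each axial slice, the longest chord between boundary
#' voxel centers of the mask, and returns the slice where that chord is
#' maximal as a [recist_annotation()] in world mm. A boundary voxel is a
#' mask voxel with fewer than four in-plane 4-neighbours inside the mask.
#' Ties (equal chord length to 1e-9 mm) are broken by the
#' lexicographically smallest canonical endpoint pair, and across slices
#' by the lower slice index.
#'
#' @param mask a `roi_mask` (e.g. the phantom's lesion truth mask).
#' @param scan_index optional temporal index stored in the annotation.
#' @return A [recist_annotation()].
#' @export
derive_recist_line <- function(mask, scan_index = NA_integer_) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$mask
  if (!any(m)) stopf("cannot derive a RECIST line from an empty mask")
  d <- dim(m)
  xs <- axis_coords(mask, 1)
  ys <- axis_coords(mask, 2)
  zs <- axis_coords(mask, 3)
  best <- NULL
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    # in-plane boundary: fewer than 4 of the 4-neighbours inside the mask
    nb <- matrix(0L, d[1], d[2])
    nb[-1, ] <- nb[-1, ] + sl[-d[1], ]
    nb[-d[1], ] <- nb[-d[1], ] + sl[-1, ]
    nb[, -1] <- nb[, -1] + sl[, -d[2]]
    nb[, -d[2]] <- nb[, -d[2]] + sl[, -1]
    bd <- which(sl & nb < 4L, arr.ind = TRUE)
    pts <- cbind(xs[bd[, 1]], ys[bd[, 2]])
    fp <- farthest_pair(pts)
    if (is.null(best) || fp$dist > best$dist + 1e-9) {
      best <- list(dist = fp$dist, p1 = fp$p1, p2 = fp$p2, k = k)
    }
  }
  recist_annotation(
    p1 = c(best$p1, zs[best$k]),
    p2 = c(best$p2, zs[best$k]),
    slice_index = best$k - 1L,
    scan_index = scan_index
  )
}
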