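# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Separable Gaussian smoothing of a 3D array. `sigma_vox` is the per-axis
# kernel sd in voxels; axes with sigma below `min_sigma` are left untouched
# (the limit of no spatial correlation). Edges are replicate-padded so the
# output has no NA rim.
smooth_gaussian <- function(arr, sigma_vox, min_sigma = 1e-3) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s < min_sigma) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    da <- dim(arr)
    m <- matrix(arr, nrow = da[1])
    m <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(da[1], r), , drop = FALSE])
    m <- stats::filter(m, k, sides = 2)
    m <- m[(r + 1L):(r + da[1]), , drop = FALSE]
    arr <- array(as.numeric(m), dim = da)
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Exact binary dilation of a 3D mask by a world-space ball of radius
# `width_mm`, computed by FFT convolution with the ball-offset kernel.
# Voxel centers whose anisotropic Euclidean distance to some mask voxel
# center is <= width_mm (+1e-9 slack for exact ties) are set.
dilate_mask_mm <- function(mask, width_mm, spacing) {
  d <- dim(mask)
  r_vox <- pmin(floor(width_mm / spacing), d - 1L)
  kd <- 2L * r_vox + 1L
  off <- expand.grid(
    x = seq(-r_vox[1], r_vox[1]),
    y = seq(-r_vox[2], r_vox[2]),
    z = seq(-r_vox[3], r_vox[3])
  )
  dist <- sqrt((off$x * spacing[1])^2 + (off$y * spacing[2])^2 + (off$z * spacing[3])^2)
  keep <- dist <= width_mm + 1e-9
  pd <- d + kd - 1L
  pd <- vapply(pd, function(n) as.integer(stats::nextn(n, c(2, 3, 5))), integer(1))
  A <- array(0, dim = pd)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- as.numeric(mask)
  K <- array(0, dim = pd)
  ix <- ((off$x[keep]) %% pd[1]) + 1L
  iy <- ((off$y[keep]) %% pd[2]) + 1L
  iz <- ((off$z[keep]) %% pd[3]) + 1L
  K[cbind(ix, iy, iz)] <- 1
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(pd)
  out <- conv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] > 0.5
  out
}

# Farthest pair of points (rows of `pts`, mm). Chunked so the full distance
# matrix is never materialised. Ties within 1e-9 are broken by choosing the
# lexicographically smallest canonical endpoint pair (p1 <= p2 row-wise).
farthest_pair <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  if (n == 1L) return(list(dist = 0, p1 = pts[1, ], p2 = pts[1, ]))
  sq <- rowSums(pts^2)
  best <- -1
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(pts[s:e, , drop = FALSE], pts)
    m <- max(d2)
    if (m > best) best <- m
  }
  best_d <- sqrt(max(best, 0))
  # second pass: gather all pairs at the maximum, canonicalise, pick smallest
  cand <- NULL
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(pts[s:e, , drop = FALSE], pts)
    hit <- which(d2 >= best - 1e-9 * max(best, 1), arr.ind = TRUE)
    if (nrow(hit)) {
      cand <- rbind(cand, cbind(hit[, 1] + s - 1L, hit[, 2]))
    }
  }
  pairs <- unique(t(apply(cand, 1, sort)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(list(dist = 0, p1 = pts[1, ], p2 = pts[1, ]))
  a <- pts[pairs[, 1], , drop = FALSE]
  b <- pts[pairs[, 2], , drop = FALSE]
  # canonical order within each pair: p1 lexicographically <= p2
  for (i in seq_len(nrow(a))) {
    cmp <- sign(a[i, ] - b[i, ])
    nz <- cmp[cmp != 0]
    if (length(nz) > 0 && nz[1] > 0) {
      tmp <- a[i, ]; a[i, ] <- b[i, ]; b[i, ] <- tmp
    }
  }
  key <- cbind(a, b)
  ord <- do.call(order, as.data.frame(key))
  list(dist = best_d, p1 = a[ord[1], ], p2 = b[ord[1], ])
}

# Mann-Whitney AUC of `scores` for binary labels (1 = positive), with tie
# handling via midranks.
auc_stat <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC sweep over candidate thresholds (classify positive when score >= t).
# Returns one row per candidate threshold with sensitivity and specificity.
roc_sweep <- function(scores, y) {
  y <- as.integer(y)
  u <- sort(unique(scores))
  thr <- c(u, max(u) + 1)
  sens <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0L] < t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

# Upper-left-corner operating point: threshold minimising the Euclidean
# distance to (FPR = 0, TPR = 1); ties broken toward higher specificity,
# then toward the higher threshold.
upper_left_threshold <- function(scores, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L || length(unique(scores)) < 2L) return(0.5)
  sw <- roc_sweep(scores, y)
  d2 <- (1 - sw$sensitivity)^2 + (1 - sw$specificity)^2
  cand <- which(d2 <= min(d2) + 1e-12)
  cand <- cand[order(-sw$specificity[cand], -sw$threshold[cand])]
  sw$threshold[cand[1]]
}

sens_spec_at <- function(scores, y, threshold) {
  y <- as.integer(y)
  c(
    sensitivity = mean(scores[y == 1L] >= threshold),
    specificity = mean(scores[y == 0L] < threshold)
  )
}
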