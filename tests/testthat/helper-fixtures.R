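# Shared fixtures: small-geometry phantoms keep the unit suite fast; the
# class-contrast parameters are the package defaults so planted effects
# are unchanged.

small_phantom_params <- function(n_cases = 4, prevalence = 0.5, seed = 1, ...) {
  phantom_params(
    n_cases = n_cases, prevalence = prevalence, seed = seed,
    grid_shape = c(64L, 64L, 16L),
    lesion_diameter_mean = 27, lesion_diameter_sd = 2,
    ...
  )
}

# uniform-lung test volume: every voxel is lung
full_lung_volume <- function(dim = c(30L, 30L, 30L), spacing = c(1, 1, 1),
                             value = -800) {
  vol <- image_volume(array(value, dim), spacing)
  list(vol = vol, lung = roi_mask(array(TRUE, dim), vol, "lung"))
}

# axis-aligned ellipsoid by direct center inclusion (test-side geometry)
ellipsoid_mask_for_test <- function(vol, center, semi) {
  idx <- which(array(TRUE, dim(vol$data)), arr.ind = TRUE)
  w <- voxel_to_world(vol, idx - 1)
  inside <- rowSums(sweep(sweep(w, 2, center), 2, semi, "/")^2) <= 1
  array(inside, dim(vol$data))
}

# independent brute-force GLCM oracle: O(n^2) double loop over ROI voxels
brute_glcm <- function(levels, offset, n_levels) {
  idx <- which(!is.na(levels), arr.ind = TRUE)
  P <- matrix(0, n_levels, n_levels)
  d <- dim(levels)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    q <- p + offset
    if (any(q < 1) || any(q > d)) next
    b <- levels[q[1], q[2], q[3]]
    if (is.na(b)) next
    a <- levels[p[1], p[2], p[3]]
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P / sum(P)
}

# independent brute-force GLRLM oracle: explicit line walk per slice
brute_glrlm <- function(levels, direction, n_levels) {
  d <- dim(levels)
  maxlen <- max(d[1], d[2])
  R <- matrix(0, n_levels, maxlen)
  dx <- direction[1]; dy <- direction[2]
  for (k in seq_len(d[3])) {
    sl <- levels[, , k]
    starts <- which(!is.na(sl), arr.ind = TRUE)
    # a run starts where the previous cell along the direction is not a
    # same-level ROI cell
    for (r in seq_len(nrow(starts))) {
      i <- starts[r, 1]; j <- starts[r, 2]
      v <- sl[i, j]
      pi <- i - dx; pj <- j - dy
      prev_same <- pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] &&
        !is.na(sl[pi, pj]) && sl[pi, pj] == v
      if (prev_same) next
      len <- 0
      while (i >= 1 && i <= d[1] && j >= 1 && j <= d[2] &&
             !is.na(sl[i, j]) && sl[i, j] == v) {
        len <- len + 1
        i <- i + dx; j <- j + dy
      }
      R[v, len] <- R[v, len] + 1
    }
  }
  R
}

# brute-force AUC by pair counting (ties count 1/2)
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# sensitivity/specificity at a threshold (classify positive when >= t)
sens_spec_at_for_test <- function(scores, y, t) {
  c(mean(scores[y == 1] >= t), mean(scores[y == 0] < t))
}

# brute-force RECIST progressive-disease evaluator (same tie tolerance
# convention as the implementation, applied scan by scan)
brute_pd <- function(lengths) {
  for (t in 2:length(lengths)) {
    nadir <- min(lengths[1:t])
    tol <- 1e-9 * max(1, nadir)
    if (lengths[t] >= 1.2 * nadir - tol && lengths[t] - nadir >= 5 - tol) return(t)
  }
  NA_integer_
}
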