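# The bootstrapped random-forest evaluation engine: repeated resampling
# with replacement at full dataset size, per-iteration correlation
# filters fitted on the training multiset only, grid-searched random
# forests scored by out-of-bag AUC, an out-of-bag upper-left operating
# point carried to the test set, and normal-theory aggregation of the
# per-iteration metrics.

#' Configuration of a bootstrap experiment
#'
#' @param n_iterations number of bootstrap iterations (default 500).
#' @param inter_corr_filter drop one member of every feature pair whose
#'   training-set Pearson correlation exceeds `inter_corr_threshold`.
#' @param inter_corr_threshold absolute-correlation threshold (default 0.80).
#' @param volume_filter drop features significantly correlated with ROI
#'   volume on the training set.
#' @param volume_r_threshold,volume_alpha volume-filter cutoffs
#'   (|r| > 0.5 and p < 0.05 by default).
#' @param rf_grid hyperparameter grid, see [default_rf_grid()].
#' @param decimate_to_prevalence if non-`NULL`, randomly drop test-set
#'   positives each iteration until the positive fraction is as close as
#'   possible to this value (population-prevalence emulation).
#' @param seed RNG seed; iteration seeds are drawn from it up front, so
#'   runs that share a seed share their bootstrap splits regardless of
#'   filter settings (paired comparisons).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_iterations = 500L,
                              inter_corr_filter = TRUE,
                              inter_corr_threshold = 0.80,
                              volume_filter = FALSE,
                              volume_r_threshold = 0.5,
                              volume_alpha = 0.05,
                              rf_grid = default_rf_grid(),
                              decimate_to_prevalence = NULL,
                              seed = 1L) {
  if (n_iterations < 2L) stopf("`n_iterations` must be >= 2")
  for (nm in c("inter_corr_threshold", "volume_r_threshold", "volume_alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) stopf("`%s` must be in (0, 1)", nm)
  }
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      inter_corr_filter = isTRUE(inter_corr_filter),
      inter_corr_threshold = inter_corr_threshold,
      volume_filter = isTRUE(volume_filter),
      volume_r_threshold = volume_r_threshold,
      volume_alpha = volume_alpha,
      rf_grid = rf_grid,
      decimate_to_prevalence = decimate_to_prevalence,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Default random-forest hyperparameter grid
#'
#' Searched exhaustively every iteration and scored by out-of-bag AUC on
#' the training multiset: trees in {100, 300, 500}, minimum node size in
#' {1, 3, 5}, and mtry in {sqrt(p), p/3}.
#'
#' @return list with `num_trees`, `min_node_size`, `mtry` (functions of p).
#' @export
default_rf_grid <- function() {
  list(
    num_trees = c(100L, 300L, 500L),
    min_node_size = c(1L, 3L, 5L),
    mtry = list(
      sqrt = function(p) max(1L, floor(sqrt(p))),
      third = function(p) max(1L, floor(p / 3))
    )
  )
}

#' One bootstrap resample: training multiset and out-of-sample test set
#'
#' Training indices are `n` draws with replacement from `1..n`; the test
#' set is the indices never drawn. An empty test set (possible only for
#' tiny `n`) triggers a redraw.
#'
#' @param n dataset size (>= 2). Uses the current RNG state.
#' @return list with `train` (length-n multiset) and `test`.
#' @export
bootstrap_split <- function(n) {
  if (n < 2L) stopf("`n` must be >= 2")
  repeat {
    train <- sample.int(n, n, replace = TRUE)
    test <- setdiff(seq_len(n), train)
    if (length(test) > 0L) return(list(train = train, test = test))
  }
}

#' Inter-feature correlation filter
#'
#' For every feature pair with training-set |Pearson r| above the
#' threshold (pairs visited in descending |r|, skipping pairs with an
#' already-removed member), the member with the smaller absolute
#' point-biserial correlation to the outcome labels is removed; ties
#' keep the lower column index. Constant features have all their
#' correlations defined as 0.
#'
#' @param X training feature matrix (rows = cases).
#' @param y outcome labels (factor or 0/1; positive = second level / 1).
#' @param threshold absolute-correlation cutoff (default 0.80).
#' @return logical keep-mask over columns of `X`.
#' @export
inter_corr_filter <- function(X, y, threshold = 0.80) {
  p <- ncol(X)
  if (p < 2L) stopf("need at least 2 features")
  y01 <- as_binary(y)
  sds <- apply(X, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  C[const, ] <- 0; C[, const] <- 0
  diag(C) <- 0
  lab_cor <- suppressWarnings(abs(as.numeric(stats::cor(X, y01))))
  lab_cor[!is.finite(lab_cor)] <- 0
  keep <- rep(TRUE, p)
  ut <- which(upper.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  if (nrow(ut)) {
    ord <- order(-abs(C[ut]))
    ut <- ut[ord, , drop = FALSE]
    for (r in seq_len(nrow(ut))) {
      a <- ut[r, 1]; b <- ut[r, 2]
      if (!keep[a] || !keep[b]) next
      drop <- if (lab_cor[a] < lab_cor[b]) a
              else if (lab_cor[b] < lab_cor[a]) b
              else max(a, b)  # tie: keep the lower column index
      keep[drop] <- FALSE
    }
  }
  keep
}

#' Volume correlation filter
#'
#' Removes features with a significant (p < `alpha`) training-set
#' Pearson correlation with ROI volume exceeding `r_threshold` in
#' absolute value.
#'
#' @param X training feature matrix.
#' @param volumes ROI volume per training case (mm^3).
#' @param r_threshold,alpha cutoffs (defaults 0.5 and 0.05).
#' @return logical keep-mask over columns of `X`.
#' @export
volume_corr_filter <- function(X, volumes, r_threshold = 0.5, alpha = 0.05) {
  apply(X, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(volumes) == 0) return(TRUE)
    ct <- suppressWarnings(stats::cor.test(col, volumes))
    !(is.finite(ct$estimate) && abs(ct$estimate) > r_threshold && ct$p.value < alpha)
  })
}

as_binary <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2]) else as.integer(y)
}

#' Grid-searched random forest with out-of-bag probabilities
#'
#' Fits a probability forest for every grid point, scores each by the
#' AUC of its out-of-bag class probabilities on the training multiset,
#' and refits nothing: the best forest, its OOB probabilities and its
#' min-max-normalized impurity importances are returned. Ties keep the
#' earlier grid point (grid enumerated trees, then node size, then mtry).
#'
#' @param X training feature matrix (training multiset rows).
#' @param y training labels (both classes must be present).
#' @param grid see [default_rf_grid()].
#' @param seed integer seed passed to the forest.
#' @return list with `model`, `oob_prob`, `importance` (in `[0, 1]`),
#'   `best`, `oob_auc`.
#' @export
train_rf <- function(X, y, grid = default_rf_grid(), seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stopf("training multiset contains a single class")
  pos <- levels(y)[nlevels(y)]
  p <- ncol(X)
  df <- as.data.frame(X)
  colnames(df) <- colnames(X) %||% paste0("f", seq_len(p))
  best <- NULL
  gi <- 0L
  for (nt in grid$num_trees) for (mns in grid$min_node_size) for (mf in grid$mtry) {
    gi <- gi + 1L
    fit <- ranger::ranger(
      x = df, y = y, num.trees = nt, min.node.size = mns, mtry = mf(p),
      probability = TRUE, importance = "impurity", num.threads = 1L,
      seed = seed + gi
    )
    oob <- fit$predictions[, pos]
    auc <- auc_stat(oob[is.finite(oob)], as_binary(y)[is.finite(oob)])
    if (is.null(best) ||
        (is.finite(auc) && (!is.finite(best$oob_auc) || auc > best$oob_auc + 1e-12))) {
      best <- list(model = fit, oob_prob = oob, oob_auc = auc,
                   best = list(num_trees = nt, min_node_size = mns, mtry = mf(p)))
    }
  }
  imp <- best$model$variable.importance
  rng <- range(imp)
  imp <- if (diff(rng) > 0) (imp - rng[1]) / diff(rng) else rep(0, length(imp))
  list(model = best$model, oob_prob = best$oob_prob, importance = imp,
       best = best$best, oob_auc = best$oob_auc)
}

#' Out-of-bag upper-left operating point
#'
#' The probability threshold minimizing the Euclidean distance to the
#' ideal ROC corner (FPR 0, TPR 1) on the out-of-bag training curve;
#' ties resolve toward higher specificity. Degenerate inputs (one class
#' or constant probabilities) fall back to 0.5.
#'
#' @param oob_prob out-of-bag positive-class probabilities.
#' @param y training labels aligned with `oob_prob`.
#' @return scalar threshold.
#' @export
oob_operating_point <- function(oob_prob, y) {
  keep <- is.finite(oob_prob)
  upper_left_threshold(oob_prob[keep], as_binary(y)[keep])
}

#' Reduce a test set to a target outcome prevalence
#'
#' Randomly drops positives until the positive fraction is as close as
#' possible to `target` (never below one positive); sets already at or
#' below the target are unchanged. Uses the current RNG state.
#'
#' @param test_idx test-set indices.
#' @param labels labels of the full dataset.
#' @param target target positive fraction.
#' @return reduced index vector.
#' @export
decimate_test <- function(test_idx, labels, target) {
  y <- as_binary(labels)[test_idx]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(test_idx)
  if (n_pos / (n_pos + n_neg) <= target) return(test_idx)
  ks <- seq_len(n_pos)
  frac <- ks / (ks + n_neg)
  k <- ks[order(abs(frac - target), -ks)][1]  # tie: keep more positives
  keep_pos <- sample(which(y == 1L), k)
  sort(c(test_idx[keep_pos], test_idx[y == 0L]))
}

#' Run the full bootstrap experiment on a feature table
#'
#' Each iteration: bootstrap split, filters fitted on the training
#' multiset, grid-searched forest, OOB operating point, test-set
#' probabilities, AUC and sensitivity/specificity at the carried
#' threshold. Iteration seeds are pre-drawn from `config$seed`, so two
#' runs with the same seed use identical splits whatever the filter
#' settings. Iterations whose training multiset is single-class are
#' skipped and logged.
#'
#' @param ft a `feature_table` from [extract_cohort()], or a list with
#'   `features`, `labels`, `volumes`.
#' @param config an [experiment_config()].
#' @return An `experiment_result`: per-iteration metrics, kept-feature
#'   masks, normalized importances, pooled test probabilities, and the
#'   [aggregate_experiment()] summary.
#' @export
run_experiment <- function(ft, config = experiment_config()) {
  X <- ft$features
  y <- ft$labels
  volumes <- ft$volumes
  n <- nrow(X)
  p <- ncol(X)
  B <- config$n_iterations
  set.seed(config$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)

  iters <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    sp <- bootstrap_split(n)
    y_tr <- y[sp$train]
    if (length(unique(as_binary(y_tr))) < 2L) {
      iters[[b]] <- list(skipped = TRUE, reason = "single-class training multiset")
      next
    }
    stopifnot(length(intersect(sp$test, unique(sp$train))) == 0L)  # leak check
    X_tr <- X[sp$train, , drop = FALSE]
    keep <- rep(TRUE, p)
    if (config$inter_corr_filter) {
      keep <- keep & inter_corr_filter(X_tr, y_tr, config$inter_corr_threshold)
    }
    if (config$volume_filter) {
      keep <- keep & volume_corr_filter(X_tr, volumes[sp$train],
                                        config$volume_r_threshold, config$volume_alpha)
    }
    if (!any(keep)) {
      iters[[b]] <- list(skipped = TRUE, reason = "filters removed all features")
      next
    }
    fit <- train_rf(X_tr[, keep, drop = FALSE], y_tr, config$rf_grid,
                    seed = iter_seeds[b] %% 100000L)
    thr <- oob_operating_point(fit$oob_prob, y_tr)
    test_idx <- sp$test
    if (!is.null(config$decimate_to_prevalence)) {
      test_idx <- decimate_test(test_idx, y, config$decimate_to_prevalence)
    }
    pr <- stats::predict(fit$model,
                         data = as.data.frame(X[test_idx, keep, drop = FALSE]))
    # ranger orders probability columns by factor level; positive = last
    prob <- pr$predictions[, ncol(pr$predictions)]
    y_te <- as_binary(y)[test_idx]
    ss <- sens_spec_at(prob, y_te, thr)
    imp_full <- rep(0, p)
    imp_full[keep] <- fit$importance
    iters[[b]] <- list(
      skipped = FALSE,
      train = sp$train, test = test_idx,
      n_unique_train = length(unique(sp$train)),
      keep = keep,
      auc = auc_stat(prob, y_te),
      sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]],
      threshold = thr,
      importance = imp_full,
      test_prob = prob, test_y = y_te,
      best = fit$best
    )
  }
  res <- aggregate_experiment(iters)
  res$config <- config
  res$feature_names <- colnames(X)
  colnames(res$importance) <- colnames(X)
  colnames(res$kept) <- colnames(X)
  res
}

#' Aggregate per-iteration bootstrap results
#'
#' The reported AUC is the mean of the per-iteration test AUCs with a
#' normal-theory 95% CI (`mean +/- 1.96 sd / sqrt(B)`); sensitivity and
#' specificity are the means at each iteration's own OOB threshold, with
#' the same CI construction. The pooled ROC (all test probabilities
#' concatenated) is reported for plotting.
#'
#' @param iters list of per-iteration records from [run_experiment()].
#' @return An object of class `experiment_result`.
#' @export
aggregate_experiment <- function(iters) {
  ok <- !vapply(iters, function(it) isTRUE(it$skipped), logical(1))
  if (sum(ok) < 2L) stopf("fewer than 2 successful iterations")
  good <- iters[ok]
  pull <- function(field) vapply(good, `[[`, numeric(1), field)
  ci <- function(x) {
    m <- mean(x)
    half <- 1.96 * stats::sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }
  aucs <- pull("auc")
  sens <- pull("sensitivity")
  spec <- pull("specificity")
  pooled_prob <- unlist(lapply(good, `[[`, "test_prob"))
  pooled_y <- unlist(lapply(good, `[[`, "test_y"))
  imp <- do.call(rbind, lapply(good, `[[`, "importance"))
  keep <- do.call(rbind, lapply(good, `[[`, "keep"))
  structure(
    list(
      auc = ci(aucs), sensitivity = ci(sens), specificity = ci(spec),
      per_iteration = data.frame(
        auc = aucs, sensitivity = sens, specificity = spec,
        threshold = pull("threshold"),
        n_unique_train = vapply(good, `[[`, integer(1), "n_unique_train"),
        n_test = vapply(good, function(it) length(it$test), integer(1))
      ),
      pooled_roc = roc_sweep(pooled_prob, pooled_y),
      pooled_auc = auc_stat(pooled_prob, pooled_y),
      importance = imp,
      kept = keep,
      n_iterations = length(good),
      n_skipped = sum(!ok),
      iterations = iters
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %d iterations: AUC %.3f [%.3f, %.3f], sens %.0f%% [%.0f%%, %.0f%%], spec %.0f%% [%.0f%%, %.0f%%]\n",
    x$n_iterations, x$auc["mean"], x$auc["lo"], x$auc["hi"],
    100 * x$sensitivity["mean"], 100 * x$sensitivity["lo"], 100 * x$sensitivity["hi"],
    100 * x$specificity["mean"], 100 * x$specificity["lo"], 100 * x$specificity["hi"]
  ))
  invisible(x)
}
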