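# helper: small synthetic feature table with two informative columns
toy_table <- function(n = 40, p = 8, effect = 2, seed = 101) {
  set.seed(seed)
  y <- factor(rep(c("rili", "recurrence"), length.out = n), levels = c("rili", "recurrence"))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, 1] <- X[, 1] + effect * (y == "recurrence")
  X[, 2] <- X[, 2] - effect * (y == "recurrence")
  list(features = X, labels = y, volumes = abs(rnorm(n, 100, 10)))
}

test_that("bootstrap splits are with-replacement resamples with disjoint test sets", {
  expect_error(bootstrap_split(1), ">= 2")
  set.seed(51)
  for (i in 1:50) {
    sp <- bootstrap_split(30)
    expect_length(sp$train, 30)
    expect_gt(length(sp$test), 0)
    expect_length(intersect(sp$test, unique(sp$train)), 0)
    expect_setequal(union(unique(sp$train), sp$test), 1:30)
  }
})

test_that("mean unique-train fraction matches the closed-form expectation", {
  # oracle: E[unique fraction] = 1 - (1 - 1/n)^n for n draws from n
  set.seed(52)
  uniq <- replicate(500, length(unique(bootstrap_split(68)$train)))
  expect_equal(mean(uniq) / 68, 1 - (1 - 1 / 68)^68, tolerance = 0.01)
})

test_that("the inter-correlation filter keeps the member more correlated with labels", {
  tt <- toy_table()
  # duplicated column: exactly one copy removed
  X <- cbind(tt$features, dup = tt$features[, 1])
  keep <- inter_corr_filter(X, tt$labels)
  expect_identical(sum(!keep), 1L)
  expect_true(xor(keep[1], keep[ncol(X)]))
  expect_true(keep[1])  # tie broken toward the lower column index

  # mutually independent features: nothing removed
  set.seed(53)
  Xi <- matrix(rnorm(60 * 6), 60, 6)
  expect_true(all(inter_corr_filter(Xi, rep(0:1, 30))))

  # crafted 3-feature table, hand-executed rule: f1-f2 highly correlated,
  # f2 closer to the labels, so f1 is removed; f3 untouched
  set.seed(54)
  y <- rep(c(0, 1), each = 25)
  base <- rnorm(50)
  f2 <- base + 1.2 * y
  f1 <- f2 + rnorm(50, sd = 0.1)
  f1 <- f1 - 1.0 * y  # degrade f1's label correlation while keeping |r(f1,f2)| high
  f3 <- rnorm(50)
  Xc <- cbind(f1 = f1, f2 = f2, f3 = f3)
  stopifnot(abs(cor(f1, f2)) > 0.8)
  want_drop <- if (abs(cor(f1, y)) < abs(cor(f2, y))) 1 else 2
  keep <- inter_corr_filter(Xc, y)
  expect_identical(which(!keep), as.integer(want_drop))
})

test_that("the volume filter matches a direct correlation-test oracle", {
  set.seed(55)
  vols <- runif(60, 50, 200)
  X <- cbind(
    v = vols,                         # the volume itself: removed
    ind = rnorm(60),                  # independent: kept
    mid = vols + rnorm(60, sd = 50)   # controlled partial correlation
  )
  keep <- volume_corr_filter(X, vols)
  expect_false(keep[1])
  expect_true(keep[2])
  ct <- cor.test(X[, 3], vols)
  expect_identical(unname(keep[3]), !(abs(ct$estimate) > 0.5 && ct$p.value < 0.05))
})

test_that("random-forest training separates a separable table and is seed-stable", {
  tt <- toy_table(effect = 3)
  fit <- train_rf(tt$features, tt$labels, seed = 7)
  expect_gt(fit$oob_auc, 0.9)
  expect_true(all(fit$importance >= 0 & fit$importance <= 1))
  expect_equal(max(fit$importance), 1)
  fit2 <- train_rf(tt$features, tt$labels, seed = 7)
  expect_identical(fit$importance, fit2$importance)
  expect_identical(fit$best, fit2$best)

  # permuted labels: OOB AUC hovers at chance
  set.seed(56)
  aucs <- replicate(5, {
    yp <- sample(tt$labels)
    train_rf(tt$features, yp, seed = sample.int(1000, 1))$oob_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
  expect_error(train_rf(tt$features, factor(rep("a", 40))), "single class")
})

test_that("the OOB operating point sits at the upper-left corner", {
  # perfectly separated probabilities: threshold attains sens = spec = 1
  y <- c(rep(0, 10), rep(1, 10))
  prob <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  thr <- oob_operating_point(prob, y)
  ss <- sens_spec_at_for_test(prob, y, thr)
  expect_equal(unname(ss), c(1, 1))

  # symmetric overlapping score distributions: threshold near the midpoint
  set.seed(57)
  y2 <- rep(c(0, 1), each = 500)
  p2 <- c(rnorm(500, 0.4, 0.1), rnorm(500, 0.6, 0.1))
  expect_lt(abs(oob_operating_point(p2, y2) - 0.5), 0.05)

  # degenerate: constant probabilities fall back to 0.5
  expect_equal(oob_operating_point(rep(0.7, 10), y), 0.5)
  expect_equal(oob_operating_point(runif(5), rep(1, 5)), 0.5)
})

test_that("aggregation reproduces hand-computed means and intervals", {
  mk_iter <- function(auc) {
    list(skipped = FALSE, train = 1:4, test = 5:6, n_unique_train = 3L,
         keep = rep(TRUE, 3), auc = auc, sensitivity = 0.6, specificity = 0.7,
         threshold = 0.5, importance = c(1, 0.5, 0), test_prob = c(0.2, 0.8),
         test_y = c(0L, 1L), best = list())
  }
  same <- aggregate_experiment(list(mk_iter(0.65), mk_iter(0.65), mk_iter(0.65)))
  expect_equal(unname(same$auc), c(0.65, 0.65, 0.65))

  two <- aggregate_experiment(list(mk_iter(0.6), mk_iter(0.7)))
  half <- 1.96 * sd(c(0.6, 0.7)) / sqrt(2)
  expect_equal(unname(two$auc), c(0.65, 0.65 - half, 0.65 + half))
  expect_equal(two$pooled_auc, 1)  # pooled probs (0.2, 0.8) separate perfectly
  expect_error(aggregate_experiment(list(mk_iter(0.6))), "fewer than 2")
})

test_that("test-set decimation hits the closest feasible positive fraction", {
  labels <- factor(c(rep("recurrence", 10), rep("rili", 10)),
                   levels = c("rili", "recurrence"))
  set.seed(58)
  # oracle: enumerate feasible fractions k/(k+10) and pick the closest to 0.10
  red <- decimate_test(1:20, labels, 0.10)
  expect_identical(sum(labels[red] == "recurrence"), 1L)
  expect_identical(sum(labels[red] == "rili"), 10L)
  # already at or below target: unchanged
  lab2 <- factor(c("recurrence", rep("rili", 19)), levels = c("rili", "recurrence"))
  expect_identical(decimate_test(1:20, lab2, 0.10), 1:20)
  # balanced set, target 0.5: unchanged
  expect_identical(decimate_test(1:20, labels, 0.5), 1:20)
})

test_that("shared seeds give identical splits across filter variants (paired design)", {
  tt <- toy_table(n = 30)
  cfg_on <- experiment_config(n_iterations = 10, inter_corr_filter = TRUE, seed = 99)
  cfg_off <- experiment_config(n_iterations = 10, inter_corr_filter = FALSE, seed = 99)
  r_on <- run_experiment(tt, cfg_on)
  r_off <- run_experiment(tt, cfg_off)
  expect_identical(
    lapply(r_on$iterations, `[[`, "train"),
    lapply(r_off$iterations, `[[`, "train")
  )
  expect_identical(
    lapply(r_on$iterations, `[[`, "test"),
    lapply(r_off$iterations, `[[`, "test")
  )
  expect_true(all(vapply(r_off$iterations, function(it) all(it$keep), logical(1))))
  # the engine recovers the planted effect on this toy table
  expect_gt(r_off$auc[["lo"]], 0.5)
  # no test case ever appears in its iteration's training multiset
  for (it in r_on$iterations) {
    expect_length(intersect(it$test, unique(it$train)), 0)
  }
})
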