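test_that("random folds are even, stratified, and deterministic", {
  y40 <- rep(c(1, -1), each = 20)
  f <- random_folds(40, 10, labels = y40, seed = 1)
  expect_true(all(table(f) == 4))

  # 20 folds over 20+20: every fold pairs one sample of each class
  f20 <- random_folds(40, 20, labels = y40, seed = 2)
  expect_true(all(table(f20) == 2))
  expect_true(all(table(f20[y40 == 1]) == 1))
  expect_true(all(table(f20[y40 == -1]) == 1))

  f10 <- random_folds(10, 4, seed = 3)
  expect_equal(sort(as.integer(table(f10)), decreasing = TRUE), c(3, 3, 2, 2))

  # per-class counts always differ by <= 1 across folds (property)
  for (seed in 1:5) {
    yy <- rep(c(1, -1), times = c(13, 17))
    ff <- random_folds(30, 4, labels = yy, seed = seed)
    expect_lte(diff(range(table(ff))), 1)
    expect_lte(diff(range(table(ff[yy == 1]))), 1)
    expect_lte(diff(range(table(ff[yy == -1]))), 1)
  }

  expect_identical(random_folds(30, 5, seed = 9), random_folds(30, 5, seed = 9))
  expect_mvpa_error(random_folds(5, 6), "exceeds")
})

test_that("cross-validation decodes separable volumes perfectly and partitions samples", {
  fix <- make_classification_volumes(fixture_spec(seed = 101))
  cv <- run_cv(fix$data, fix$labels, fix$folds)
  expect_equal(glance(cv)$accuracy, 1.0)
  expect_equal(glance(cv)$auc, 1.0)
  # each sample predicted exactly once
  expect_setequal(cv$predictions$sample, seq_len(40))
  expect_equal(cv$predictions$fold, fix$folds)
  # aggregate counts equal the sum of per-fold counts
  pf <- tidy(cv)
  expect_equal(colSums(pf[, c("tp", "tn", "fp", "fn")]),
               c(tp = cv$counts[["tp"]], tn = cv$counts[["tn"]],
                 fp = cv$counts[["fp"]], fn = cv$counts[["fn"]]))
  # pooled accuracy equals the sample-weighted mean of per-fold accuracies
  expect_equal(glance(cv)$accuracy,
               sum(pf$accuracy * pf$n_test) / sum(pf$n_test))
  # mean weights are the elementwise mean of the per-fold weight vectors
  expect_equal(cv$weights$mean, colMeans(cv$weights$per_fold))
})

test_that("duplicated halves give two identical folds", {
  dat <- sep_matrix_data(8, 6, d = 2, seed = 61)
  x2 <- rbind(dat$x, dat$x)
  y2 <- c(dat$labels, dat$labels)
  folds <- rep(c(1, 2), each = 16)
  cv <- run_cv(x2, y2, folds)
  pf <- tidy(cv)
  expect_equal(pf$accuracy[1], pf$accuracy[2])
  expect_equal(pf[1, c("tp", "tn", "fp", "fn")],
               pf[2, c("tp", "tn", "fp", "fn")], ignore_attr = TRUE)
})

test_that("label-permuted decoding stays at chance", {
  fix <- make_classification_volumes(fixture_spec(seed = 71))
  accs <- vapply(1:50, function(s) {
    yp <- withr::with_seed(5000 + s, sample(fix$labels))
    glance(run_cv(fix$data, yp, fix$folds))$accuracy
  }, numeric(1))
  # mean over 50 seeded permutations inside the central 99% binomial band
  half <- 2.576 * sqrt(0.25 / (50 * 40))
  expect_lt(abs(mean(accs) - 0.5), half + 0.01)
})

test_that("perturbing a test fold changes nothing fitted for that fold", {
  dat <- sep_matrix_data(10, 12, d = 2, seed = 81)
  folds <- random_folds(20, 4, labels = dat$labels, seed = 1)
  pre <- list(step_zscore(), step_pca(0.9), step_select("fscore", fraction = 0.5))
  cv1 <- run_cv(dat$x, dat$labels, folds, preprocess = pre, seed = 3)
  x_pert <- dat$x
  x_pert[folds == 2, ] <- x_pert[folds == 2, ] + 100
  cv2 <- run_cv(x_pert, dat$labels, folds, preprocess = pre, seed = 3)
  # fold 2's model was trained without fold 2: identical weights and offset
  expect_equal(cv1$weights$per_fold[2, ], cv2$weights$per_fold[2, ])
  expect_equal(cv1$weights$b_per_fold[2], cv2$weights$b_per_fold[2])
})

test_that("a training split missing a class is refused by name", {
  dat <- sep_matrix_data(4, 3, d = 1, seed = 91)
  # fold 1 holds every -1 sample, so fold 1's training split sees only +1
  folds <- c(1, 1, 1, 2, 1, 1, 1, 1)
  expect_mvpa_error(run_cv(dat$x, dat$labels, folds), "fold 1")
})

test_that("confusion metrics match their definitions and undefined cases stay NA", {
  # the unique counts consistent with 85/95/75% at 20 patients + 20 controls
  m <- confusion_metrics(tp = 19, tn = 15, fp = 5, fn = 1)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.75)
  expect_equal(unlist(confusion_metrics(tp = 10, tn = 10, fp = 0, fn = 0)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(unlist(confusion_metrics(tp = 0, tn = 0, fp = 10, fn = 10)),
               c(accuracy = 0, sensitivity = 0, specificity = 0))
  # no positives at all: sensitivity undefined, not 0
  m2 <- confusion_metrics(tp = 0, tn = 8, fp = 2, fn = 0)
  expect_true(is.na(m2$sensitivity))
  expect_equal(m2$specificity, 0.8)
})

test_that("AUC equals the pairwise concordance statistic", {
  # brute-force oracle: P(s+ > s-) + 0.5 P(s+ = s-)
  concordance <- function(dv, y) {
    sp <- dv[y == 1]; sn <- dv[y == -1]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  dv <- c(0.9, 0.4, 0.4, 0.2, -0.1, -0.5)
  y <- c(1, 1, -1, 1, -1, -1)
  expect_equal(roc_auc(dv, y)$auc, concordance(dv, y))
  for (seed in 1:5) {
    withr::with_seed(seed, {
      dvr <- round(rnorm(20), 1) # rounding forces ties
      yr <- rep(c(1, -1), 10)
    })
    expect_equal(roc_auc(dvr, yr)$auc, concordance(dvr, yr))
  }
  expect_equal(roc_auc(c(3, 2, -1, -2), c(1, 1, -1, -1))$auc, 1.0)
  expect_mvpa_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  # label-independent scores: mean AUC near 0.5
  aucs <- vapply(1:50, function(s) {
    withr::with_seed(900 + s, roc_auc(rnorm(40), rep(c(1, -1), 20))$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("prediction precision is the Pearson correlation of pooled predictions", {
  expect_equal(prediction_precision(1:5, 1:5), 1)
  expect_equal(prediction_precision(-(1:5), 1:5), -1)
  expect_equal(prediction_precision(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_mvpa_error(prediction_precision(rep(1, 4), 1:4), "zero variance")
  expect_mvpa_error(prediction_precision(1:2, 1:2), "at least 3")
})

test_that("regression cross-validation recovers a strong voxel-score coupling", {
  spec <- fixture_spec(task = "regress", regression_slope = 8, noise_sd = 0.5,
                       folds = 5, seed = 111)
  fix <- make_regression_volumes(spec)
  cv <- run_cv(fix$data, fix$scores, fix$folds,
               model = make_model("svm", task = "regress"))
  expect_gt(glance(cv)$r, 0.9)
  expect_equal(nrow(cv$predictions), 20L)
})
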