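test_that("model specs carry the printed defaults and reject bad combinations", {
  svc <- make_model("svm")
  expect_equal(svc$params[c("type", "kernel", "c")],
               list(type = "c-svc", kernel = "linear", c = 1))
  expect_equal(svc$params[c("g", "d", "r", "nu")],
               list(g = 0.1, d = 3, r = 0, nu = 0.5))
  svr <- make_model("svm", task = "regress")
  expect_equal(svr$params[c("type", "kernel", "c", "p")],
               list(type = "eps-svr", kernel = "linear", c = 1, p = 0.1))
  expect_equal(make_model("knn")$params$k, 11L)
  expect_equal(make_model("knn", k = 5)$params$k, 5)
  expect_equal(make_model("forest")$params$n_trees, 500L)
  expect_mvpa_error(make_model("lda", task = "regress"), "classification only")
  expect_mvpa_error(make_model("logistic", task = "regress"), "classification only")
  expect_mvpa_error(make_model("svm", cost = 2), "unknown parameter")
  expect_mvpa_error(make_model("svm", type = "eps-svr"), "does not match task")
})

test_that("a symmetric separable problem yields a symmetric linear SVM", {
  x <- matrix(c(10, -10), ncol = 1)
  y <- c(1, -1)
  m <- fit_model(make_model("svm"), x, y)
  lw <- linear_weights(m)
  expect_gt(lw$w, 0)
  expect_equal(lw$b, 0, tolerance = 1e-6)
  expect_equal(predict_model(m, x)$.pred, y)
})

test_that("KNN votes, tie rules, and self-prediction behave as documented", {
  dat <- sep_matrix_data(10, 3, d = 3, seed = 5)
  m1 <- fit_model(make_model("knn", k = 1), dat$x, dat$labels)
  expect_equal(predict_model(m1, dat$x)$.pred, dat$labels)

  # 6 votes vs 5 at k = 11: majority class, probability 6/11
  xtr <- matrix(c(rep(1, 6), rep(1.1, 5)), ncol = 1)
  ytr <- c(rep(1, 6), rep(-1, 5))
  m11 <- fit_model(make_model("knn"), xtr, ytr)
  pr <- predict_model(m11, matrix(0, 1, 1))
  expect_equal(pr$.pred, 1)
  expect_equal(pr$probability, 6 / 11)
  expect_equal(pr$decision_value, 1 / 11)

  # even k, equal votes: decision value 0 resolves deterministically to +1
  m2 <- fit_model(make_model("knn", k = 2), matrix(c(-1, 1), 2, 1), c(-1, 1))
  pr2 <- predict_model(m2, matrix(0, 1, 1))
  expect_equal(pr2$decision_value, 0)
  expect_equal(pr2$.pred, 1)

  # distance tie at the k-th neighbor: the lower-index training sample wins
  xtie <- matrix(c(0, 2, -2), ncol = 1) # samples 2 and 3 equidistant from 0
  m3 <- fit_model(make_model("knn", k = 2), xtie, c(1, 1, -1))
  expect_equal(predict_model(m3, matrix(0, 1, 1))$probability, 1) # picked 1,2

  # regression: mean of the k neighbors
  mr <- fit_model(make_model("knn", task = "regress", k = 2),
                  matrix(c(0, 1, 10), 3, 1), c(2, 4, 100))
  expect_equal(predict_model(mr, matrix(0.4, 1, 1))$.pred, 3)
})

test_that("probabilistic classifiers expose coherent probabilities and decision values", {
  dat <- sep_matrix_data(15, 4, d = 2, seed = 6)
  for (alg in c("logistic", "naive_bayes", "tree", "forest")) {
    m <- fit_model(make_model(alg), dat$x, dat$labels, seed = 2)
    pr <- predict_model(m, dat$x)
    expect_equal(pr$decision_value, 2 * (pr$probability - 0.5),
                 tolerance = 1e-12, label = alg)
    expect_true(all(pr$.pred == ifelse(pr$decision_value >= 0, 1, -1)),
                label = alg)
  }
})

test_that("Gaussian naive Bayes approaches the closed-form Bayes rate", {
  # two unit-variance 1-D Gaussians 2 SD apart: Bayes accuracy Phi(1) = 0.841
  withr::with_seed(77, {
    x <- matrix(c(rnorm(200, 1), rnorm(200, -1)), ncol = 1)
  })
  y <- rep(c(1, -1), each = 200)
  m <- fit_model(make_model("naive_bayes"), x, y)
  acc <- mean(predict_model(m, x)$.pred == y)
  bayes <- pnorm(1)
  expect_lt(abs(acc - bayes), 3 * sqrt(bayes * (1 - bayes) / 400))
})

test_that("forest predictions are the average of their trees", {
  withr::with_seed(41, {
    x <- matrix(rnorm(30 * 3), 30)
    y <- x[, 1] + rnorm(30, sd = 0.2)
  })
  m <- fit_model(make_model("forest", task = "regress", n_trees = 100), x, y,
                 seed = 9)
  pr <- predict_model(m, x)
  per_tree <- predict(m$fit$backend, x, predict.all = TRUE)$individual
  expect_equal(pr$.pred, unname(rowMeans(per_tree)), tolerance = 1e-10)
})

test_that("trees and forests reproduce a constant training target exactly", {
  x <- withr::with_seed(4, matrix(rnorm(20 * 3), 20))
  y <- rep(3.5, 20)
  for (alg in c("tree", "forest")) {
    # randomForest warns about the degenerate constant response; that is fine
    m <- suppressWarnings(fit_model(make_model(alg, task = "regress"), x, y,
                                    seed = 1))
    expect_equal(predict_model(m, x)$.pred, rep(3.5, 20), label = alg)
  }
})

test_that("linear weights reproduce decision values and split under duplication", {
  dat <- sep_matrix_data(15, 6, d = 2, seed = 13)
  m <- fit_model(make_model("svm"), dat$x, dat$labels)
  lw <- linear_weights(m)
  probes <- withr::with_seed(14, matrix(rnorm(100 * 6), 100))
  pr <- predict_model(m, probes)
  expect_equal(pr$decision_value, as.numeric(probes %*% lw$w + lw$b),
               tolerance = 1e-6)
  # duplicated feature: the copies share the original weight about equally
  xd <- cbind(dat$x, dat$x[, 1])
  lwd <- linear_weights(fit_model(make_model("svm"), xd, dat$labels))
  expect_equal(lwd$w[1], lwd$w[7], tolerance = 1e-4)
  expect_equal(lwd$w[1] + lwd$w[7], lw$w[1], tolerance = 0.05 * abs(lw$w[1]) + 1e-4)

  expect_mvpa_error(
    linear_weights(fit_model(make_model("svm", kernel = "radial"),
                             dat$x, dat$labels)),
    "weights undefined")
  expect_mvpa_error(linear_weights(fit_model(make_model("knn"),
                                             dat$x, dat$labels)),
                    "weights undefined")
  # logistic and LDA expose the affine discriminant, sign-coherent with dv
  for (alg in c("logistic", "lda")) {
    mm <- suppressWarnings(fit_model(make_model(alg), dat$x, dat$labels))
    lwa <- linear_weights(mm)
    s <- as.numeric(probes %*% lwa$w + lwa$b)
    expect_equal(sign(s)[s != 0],
                 sign(predict_model(mm, probes)$decision_value)[s != 0],
                 label = alg)
  }
})

test_that("swapping the class labels negates the decision function", {
  dat <- sep_matrix_data(12, 5, d = 1.5, seed = 23)
  probes <- withr::with_seed(24, matrix(rnorm(20 * 5), 20))
  for (alg in c("svm", "lda", "logistic", "knn")) {
    m1 <- suppressWarnings(fit_model(make_model(alg), dat$x, dat$labels))
    m2 <- suppressWarnings(fit_model(make_model(alg), dat$x, -dat$labels))
    d1 <- predict_model(m1, probes)$decision_value
    d2 <- predict_model(m2, probes)$decision_value
    expect_equal(d1, -d2, tolerance = 1e-6, label = alg)
    expect_equal(mean(predict_model(m1, dat$x)$.pred == dat$labels),
                 mean(predict_model(m2, dat$x)$.pred == -dat$labels),
                 label = alg)
  }
})

test_that("fits are deterministic given data, spec and seed", {
  dat <- sep_matrix_data(15, 5, d = 1, seed = 30)
  f1 <- predict_model(fit_model(make_model("forest"), dat$x, dat$labels, seed = 3),
                      dat$x)
  f2 <- predict_model(fit_model(make_model("forest"), dat$x, dat$labels, seed = 3),
                      dat$x)
  expect_identical(f1, f2)
})

test_that("LDA regularizes a singular covariance with a warning and advice", {
  # p > n forces singular pooled covariance
  dat <- sep_matrix_data(5, 20, d = 3, seed = 55)
  expect_warning(m <- fit_model(make_model("lda"), dat$x, dat$labels),
                 "singular")
  expect_equal(predict_model(m, dat$x)$.pred, dat$labels)
})
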