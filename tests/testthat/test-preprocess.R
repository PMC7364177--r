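test_that("Z-scoring uses training statistics, population SD, and inert constants", {
  train <- cbind(c(1, 2, 3), c(5, 5, 5))
  test <- cbind(c(4), c(9))
  z <- zscore_fit_apply(train, test, direction = "columns")
  s <- sqrt(2 / 3) # population SD of (1,2,3)
  expect_equal(z$params$m, c(2, 5))
  expect_equal(z$params$sigma, c(s, 0))
  expect_equal(z$train[, 1], (c(1, 2, 3) - 2) / s)
  expect_equal(mean(z$train[, 1]), 0)
  expect_equal(mean(z$train[, 1]^2), 1) # unit population variance
  # test transformed with the TRAINING mean/SD
  expect_equal(z$test[1, 1], (4 - 2) / s)
  # sigma = 0 column maps to 0 in both splits, not NaN
  expect_equal(z$train[, 2], c(0, 0, 0))
  expect_equal(z$test[1, 2], 0)

  # row direction: each sample self-normalized with its own population SD
  zr <- zscore_fit_apply(matrix(c(2, 4, 6), nrow = 1), direction = "rows")
  expect_equal(as.numeric(zr$train), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("Z-score parameters are leakage-free", {
  dat <- sep_matrix_data(10, 6, d = 1, seed = 3)
  z1 <- zscore_fit_apply(dat$x, dat$x * 0 + 100)
  z2 <- zscore_fit_apply(dat$x, dat$x * 2 - 50)
  expect_identical(z1$params, z2$params)
})

test_that("PCA keeps the smallest component set reaching the variance target", {
  # all variance on feature 1
  x <- cbind(c(-3, -1, 1, 3), c(1, 1, 1, 1) * 1e-9)
  expect_equal(pca_fit(x, var_threshold = 0.95)$n_kept, 1L)

  # tau = 1 keeps everything computable: min(n_train - 1, p)
  xf <- withr::with_seed(5, matrix(rnorm(6 * 10), 6))
  expect_equal(pca_fit(xf, var_threshold = 1)$n_kept, 5L)
  expect_mvpa_error(pca_fit(xf, n_components = 6), "between 1 and 5")

  # kept-variance rule: >= tau at n_kept, < tau at n_kept - 1
  for (seed in 1:5) {
    xs <- withr::with_seed(seed, matrix(rnorm(8 * 6), 8))
    pp <- pca_fit(xs, var_threshold = 0.8)
    expect_gte(sum(pp$explained), 0.8)
    if (pp$n_kept > 1) expect_lt(sum(pp$explained[-pp$n_kept]), 0.8)
  }
})

test_that("PCA loadings and projections match the eigendecomposition oracle", {
  x <- withr::with_seed(11, matrix(rnorm(6 * 10), 6))
  pp <- pca_fit(x, var_threshold = 1)
  # oracle: eigenvectors of the column-centered covariance
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(xc), symmetric = TRUE)
  for (j in seq_len(pp$n_kept)) {
    expect_equal(abs(sum(pp$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8) # equal up to sign
  }
  # held-out projection equals (x - train_mean) %*% loadings
  xnew <- withr::with_seed(12, matrix(rnorm(3 * 10), 3))
  sc <- pca_apply(pp, xnew)
  expect_equal(sc, sweep(xnew, 2, colMeans(x)) %*% pp$loadings)
  # the training mean itself scores 0 on every component
  expect_equal(as.numeric(pca_apply(pp, matrix(colMeans(x), 1))),
               rep(0, pp$n_kept), tolerance = 1e-12)
  # full-rank reconstruction: centered data recoverable by inverse projection
  rec <- pca_apply(pp, x) %*% t(pp$loadings)
  expect_equal(rec, xc, tolerance = 1e-8)
  expect_mvpa_error(pca_apply(pp, xnew[, 1:4]), "does not match")
})

test_that("F scores match the hand ANOVA and its degenerate limits", {
  # class A = (0,1), class B = (2,3): MSbetween = 4, MSwithin = 0.5, F = 8
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  y <- c(1, 1, -1, -1)
  expect_equal(fscore_rank(x, y), 8)
  # agrees with R's own one-way ANOVA on random data
  xr <- withr::with_seed(8, matrix(rnorm(12 * 4), 12))
  yr <- rep(c(1, -1), each = 6)
  fr <- fscore_rank(xr, yr)
  for (j in 1:4) {
    a <- stats::anova(stats::lm(xr[, j] ~ factor(yr)))
    expect_equal(fr[j], a$`F value`[1], tolerance = 1e-10)
  }
  # identical distributions in both classes -> F = 0
  xc <- matrix(rep(c(1, 2), 4), ncol = 1)
  expect_equal(fscore_rank(xc, rep(c(1, -1), each = 4)), 0)
  # distinct means, zero within-class variance -> F = Inf, ranked first
  xi <- cbind(rep(c(1, 0), each = 4), withr::with_seed(9, rnorm(8)))
  f <- fscore_rank(xi, rep(c(1, -1), each = 4))
  expect_equal(f[1], Inf)
  expect_equal(select_features(f, n = 1), 1L, ignore_attr = TRUE)
  # invariance under adding a constant to a feature
  expect_equal(fscore_rank(xr + 100, yr), fr, tolerance = 1e-8)
})

test_that("weight ranking tracks the linear model and rejects non-linear kernels", {
  dat <- sep_matrix_data(15, 8, d = 4, n_signal = 1, seed = 21)
  sc <- weight_rank(dat$x, dat$labels)
  expect_equal(which.max(sc), 1L)
  # duplicated columns share the weight symmetrically
  xd <- cbind(dat$x, dat$x[, 1])
  sc2 <- weight_rank(xd, dat$labels)
  expect_equal(sc2[1], sc2[9], tolerance = 1e-6)
  expect_mvpa_error(weight_rank(dat$x, dat$labels,
                                model = make_model("svm", kernel = "radial")),
                    "weights undefined")
})

test_that("top-feature selection respects amounts, ties and nesting", {
  sc <- c(5, 3, 9, 1, 9, 2, 8, 7, 6, 4)
  expect_equal(as.integer(select_features(sc, n = 3)), c(3L, 5L, 7L))
  # fraction: floor(f * p), minimum 1
  sc100 <- withr::with_seed(2, runif(100))
  top10 <- select_features(sc100, fraction = 0.10)
  expect_length(top10, 10L)
  expect_setequal(as.integer(top10), order(-sc100)[1:10])
  expect_length(select_features(sc100, fraction = 0.001), 1L)
  # fraction 1.0 keeps everything
  expect_setequal(as.integer(select_features(sc100, fraction = 1)), 1:100)
  # equal scores -> index tie-break
  expect_equal(as.integer(select_features(rep(1, 5), n = 3)), 1:3)
  # nesting: top-n is a prefix of top-(n+1)
  for (n in 1:9) {
    expect_equal(as.integer(select_features(sc, n = n)),
                 as.integer(select_features(sc, n = n + 1))[1:n])
  }
  expect_mvpa_error(select_features(sc, n = 11), "cannot select")
  expect_mvpa_error(select_features(sc, n = 3, fraction = 0.5), "exactly one")
})

test_that("LASSO selection honors the penalty limits and recovers true supports", {
  withr::with_seed(31, {
    x <- matrix(rnorm(100 * 20), 100)
    y <- 2 * x[, 1] - 3 * x[, 2] + rnorm(100, sd = 0.1)
  })
  # unpenalized limit: everything survives
  expect_setequal(as.integer(lasso_select(x, y, lambda = 0)), 1:20)
  # full-shrinkage limit: explicit error, no silent fallback
  expect_mvpa_error(lasso_select(x, y, lambda = 1e6), "empty selection")
  # recovery simulation: y = 2 x1 - 3 x2 + noise, 50 repetitions
  hit <- 0L
  for (rep in 1:50) {
    withr::with_seed(1000 + rep, {
      xr <- matrix(rnorm(100 * 20), 100)
      yr <- 2 * xr[, 1] - 3 * xr[, 2] + rnorm(100, sd = 0.1)
    })
    sel <- lasso_select(xr, yr, seed = rep)
    if (all(c(1L, 2L) %in% sel)) hit <- hit + 1L
  }
  expect_gte(hit / 50, 0.95)
})
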