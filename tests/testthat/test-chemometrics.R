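test_that("mean centering is exact, idempotent and invertible", {
  X <- cbind(c(1, 3), c(10, 20))
  cen <- mean_center(X, c(5, 7))
  expect_equal(cen$X[, 1], c(-1, 1))
  expect_lt(max(abs(colMeans(cen$X))), 1e-12)
  twice <- mean_center(cen$X)
  expect_equal(twice$X, cen$X, tolerance = 1e-15)
  restored <- sweep(cen$X, 2, cen$x_means, "+")
  expect_equal(restored, X, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCA satisfies its algebraic identities", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30)
  p <- fit_pca(X, 8)
  expect_lt(max(abs(crossprod(p$loadings) - diag(8))), 1e-10)
  expect_true(all(diff(p$explained_all) <= 1e-12))
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, sweep(X, 2, p$means), tolerance = 1e-8,
               ignore_attr = TRUE)

  r1 <- tcrossprod(rnorm(20), rnorm(5))
  expect_equal(fit_pca(r1, 1)$explained[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(X, 31), "n_pc")
})

test_that("PC1 loading opposes phosphate and amide regions on cohort spectra", {
  dm <- quick_ftir_cohort(seed = 2, n_donors = 20)
  p <- fit_pca(dm$X, 2)
  po4 <- dm$wavenumber >= 900 & dm$wavenumber <= 1200
  amide <- dm$wavenumber >= 1510 & dm$wavenumber <= 1712
  l1 <- p$loadings[, 1]
  expect_lt(mean(l1[po4]) * mean(l1[amide]), 0)
})

test_that("Kennard-Stone splitting is deterministic max-min selection", {
  set.seed(10)
  X <- matrix(rnorm(120 * 6), 120)
  ks <- kennard_stone_split(X, 0.7)
  expect_equal(length(ks$calibration), 84)
  expect_equal(length(ks$prediction), 36)
  expect_equal(sort(c(ks$calibration, ks$prediction)), 1:120)
  expect_identical(ks, kennard_stone_split(X, 0.7))

  line <- matrix(0:9, ncol = 1)
  expect_equal(kennard_stone_split(line, 0.2)$calibration, c(1L, 10L))
  expect_error(kennard_stone_split(X, 1.2), "calibration_fraction")
})

test_that("NIPALS PLS recovers exact linear models and the OLS limit", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40)
  beta <- c(2, -1, 0.5, 3, -2)
  y <- drop(X %*% beta) + 7
  fit <- pls_fit(X, y, 5)
  expect_lt(max(abs(pls_predict(fit, X) - y)), 1e-8)

  # independent oracle: least squares at full rank
  y2 <- y + rnorm(40, 0, 3)
  ols <- lm(y2 ~ X)
  fit2 <- pls_fit(X, y2, 5)
  expect_equal(unname(pls_predict(fit2, X)), unname(fitted(ols)),
               tolerance = 1e-6)

  # single predictor, one LV: simple regression slope
  x1 <- matrix(rnorm(25), ncol = 1)
  y3 <- rnorm(25)
  f1 <- pls_fit(x1, y3, 1)
  expect_equal(f1$coef, cov(x1[, 1], y3) / var(x1[, 1]), tolerance = 1e-10)

  expect_error(pls_fit(X, rep(1, 40), 2), "zero-variance")
  expect_error(pls_fit(X, y, 9), "n_lv")
})

test_that("PLS scores are mutually orthogonal", {
  set.seed(5)
  X <- matrix(rnorm(30 * 12), 30)
  y <- rnorm(30)
  fit <- pls_fit(X, y, 6)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("venetian blinds assign interleaved folds and validate exactly", {
  folds <- osteospectra:::venetian_folds(40, 20)
  expect_true(all(table(folds) == 2))
  expect_equal(folds[1:4], folds[21:24])

  set.seed(6)
  X <- matrix(rnorm(60 * 6), 60)
  y <- drop(X %*% c(1, 2, 3, -1, 0.5, 2)) + 10
  cv <- venetian_blinds_cv(X, y, max_lv = 6, n_folds = 20)
  expect_lt(cv$rmsecv[6], 1e-6)
  expect_true(all(cv$rmsecv >= 0))
  expect_lte(cv$rmsecv[cv$chosen_lv], cv$rmsecv[1])
  expect_error(venetian_blinds_cv(X, y, max_lv = 50, n_folds = 20),
               "capacity")
})

test_that("regression metrics match hand-computed values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  y <- c(4, 6, 8)
  expect_equal(regression_metrics(y, rep(mean(y), 3))$r2, 0)
  # y=(0,1,2), yhat=(0,1,5): residuals (0,0,3), MSE 3, SStot 2
  m2 <- regression_metrics(c(0, 1, 2), c(0, 1, 5))
  expect_equal(m2$rmse, sqrt(3))
  expect_equal(m2$r2, -3.5)
  expect_error(regression_metrics(rep(1, 3), 1:3), "constant")
})

test_that("VIP scores obey the normalisation identity and rank signal", {
  set.seed(12)
  X <- matrix(rnorm(50 * 20), 50)
  y <- rnorm(50)
  fit <- pls_fit(X, y, 5)
  v <- vip_scores(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)

  f1 <- pls_fit(matrix(rnorm(30), ncol = 1), rnorm(30), 1)
  expect_equal(vip_scores(f1), 1, tolerance = 1e-12)

  # planted signal: 5 informative channels of 200 top the VIP ranking
  hits <- vapply(1:50, function(sd) {
    set.seed(1000 + sd)
    Xs <- matrix(rnorm(60 * 200), 60)
    ys <- rnorm(60, 35, 20)
    z <- (ys - mean(ys)) / sd(ys)
    inf <- c(10, 50, 90, 130, 170)
    Xs[, inf] <- Xs[, inf] * 0.2 + outer(z, runif(5, 0.8, 1.2))
    fit_s <- pls_fit(Xs, ys, 3)
    all(order(vip_scores(fit_s), decreasing = TRUE)[1:5] %in% inf)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
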