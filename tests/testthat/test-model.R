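test_that("NIPALS recovers a single exact latent factor", {
  set.seed(61)
  t0 <- rnorm(15)
  w <- rnorm(30); w <- w / sqrt(sum(w^2))
  X <- outer(t0, w)
  fit <- nipals_pls_fit(X, t0, 1)
  expect_equal(pls_predict(fit, X), t0, tolerance = 1e-10)
  # asking for a second component must fail with the achievable count
  expect_error(nipals_pls_fit(X, t0, 2), "achievable A is 1")
})

test_that("NIPALS agrees with the SVD-based PLS1 oracle", {
  set.seed(62)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- rnorm(20)
    A <- sample(1:5, 1)
    fit <- nipals_pls_fit(X, y, A)
    ora <- pls1_svd_oracle(X, y, A)
    # sign convention matches, so direct comparison is valid
    expect_equal(fit$weights, ora$weights, tolerance = 1e-8)
    expect_equal(fit$loadings, ora$loadings, tolerance = 1e-8)
    expect_equal(fit$scores, ora$scores, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(pls_predict(fit, X), ora$fitted, tolerance = 1e-8)
  }
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(63)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rnorm(10)
  fit <- nipals_pls_fit(X, y, 4)
  expect_equal(pls_predict(fit, X), ols_fitted_oracle(X, y), tolerance = 1e-8)
})

test_that("training scores are mutually orthogonal", {
  set.seed(64)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  fit <- nipals_pls_fit(X, y, 5)
  G <- crossprod(fit$scores)
  nrm <- sqrt(diag(G))
  off <- abs(G / outer(nrm, nrm))
  diag(off) <- 0
  expect_lt(max(off), 1e-8)
})

test_that("pls_transform is the affine projection about the centre", {
  set.seed(65)
  X <- matrix(rnorm(12 * 9), 12, 9)
  y <- rnorm(12)
  fit <- nipals_pls_fit(X, y, 3)
  expect_equal(pls_transform(fit, X), fit$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.numeric(pls_transform(fit, fit$x_mean)), rep(0, 3),
               tolerance = 1e-12)
  x <- X[4, ]
  expect_equal(pls_transform(fit, 2 * x - fit$x_mean),
               2 * pls_transform(fit, x), tolerance = 1e-10)
  expect_error(pls_transform(fit, matrix(0, 2, 5)), "columns")
})

test_that("rbf_kernel has the Gaussian closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.7), 1)
  # squared distance 2 * sigma2 -> exp(-1)
  expect_equal(rbf_kernel(0, sqrt(2 * 0.9), 0.9), exp(-1))
  set.seed(66)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(rbf_kernel(a, b, 2), rbf_kernel(b, a, 2))
  expect_error(rbf_kernel(a, b, 0), "sigma2")
})

test_that("LS-SVM solves its dual system and satisfies KKT", {
  # constant response: alpha = 0, b = c
  Tm <- cbind(c(0, 1, 2, 4))
  fit <- lssvm_fit(Tm, rep(3.5, 4), gamma = 2, sigma2 = 1)
  expect_equal(fit$alpha, rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$b, 3.5)
  expect_equal(predict(fit, cbind(1.7)), 3.5, tolerance = 1e-10)

  # two-point system solved independently as a 3x3 linear system
  k <- exp(-1)  # ||0 - 1||^2 / (2 * 0.5)
  M <- rbind(c(0, 1, 1), c(1, 2, k), c(1, k, 2))
  ref <- solve(M, c(0, 0, 1))
  fit2 <- lssvm_fit(cbind(c(0, 1)), c(0, 1), gamma = 1, sigma2 = 0.5)
  expect_equal(fit2$b, ref[1], tolerance = 1e-10)
  expect_equal(fit2$alpha, ref[-1], tolerance = 1e-10)

  # KKT identities on random fits
  set.seed(67)
  for (rep in 1:8) {
    n <- sample(5:25, 1)
    Tm <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    gamma <- 10^runif(1, -1, 3)
    fit <- lssvm_fit(Tm, y, gamma, sigma2 = runif(1, 0.5, 5))
    resid <- y - predict(fit, Tm)
    expect_lt(abs(sum(fit$alpha)) / max(sum(abs(fit$alpha)), 1), 1e-8)
    expect_equal(fit$alpha, gamma * resid, tolerance = 1e-8)
  }
})

test_that("vanishing ridge interpolates; growing gamma never hurts PRESS", {
  # well-separated points keep the near-interpolation system conditioned
  Tm <- cbind(c(0, 0.7, 1.9, 3.2, 5))
  yv <- c(0.1, 1.4, 0.2, 2.2, 1.1)
  fit <- lssvm_fit(Tm, yv, gamma = 1e8, sigma2 = 1)
  expect_lt(max(abs(predict(fit, Tm) - yv)), 1e-4)

  case <- scores_regression_case(n = 20, A = 1, seed = 68)

  p_prev <- Inf
  for (g in 10^seq(-2, 6)) {
    f <- lssvm_fit(case$T, case$y, g, sigma2 = 1)
    p_now <- press(case$y, predict(f, case$T))
    expect_lte(p_now, p_prev + 1e-8)
    p_prev <- p_now
  }
})

test_that("LS-SVM matches the direct-construction oracle", {
  case <- scores_regression_case(n = 30, A = 3, seed = 69)
  fit <- lssvm_fit(case$T, case$y, gamma = 50, sigma2 = 2)
  ora <- lssvm_oracle(case$T, case$y, gamma = 50, sigma2 = 2)
  expect_equal(fit$alpha, ora$alpha, tolerance = 1e-8)
  expect_equal(fit$b, ora$b, tolerance = 1e-8)
  expect_equal(predict(fit, case$T), ora$fitted, tolerance = 1e-8)
})

test_that("hybrid composition is consistent and fits clean data", {
  world <- small_world(n = 30, seed = 70, noise = 0, clean = TRUE)
  fit <- hybrid_fit(world$X, world$y, A = 1, gamma = 1e4, sigma2 = 10)
  preds <- predict(fit, world$X)
  expect_equal(preds, predict(fit$lssvm, fit$pls$scores),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(r2_score(world$y, preds), 0.999)

  # full hybrid against an independent end-to-end oracle
  ora_pls <- pls1_svd_oracle(world$X, world$y, 1)
  ora <- lssvm_oracle(ora_pls$scores, world$y, gamma = 1e4, sigma2 = 10)
  expect_equal(preds, ora$fitted, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("weakly-regularised wide-kernel hybrid approaches linear PLS", {
  world <- small_world(n = 35, seed = 71, noise = 1e-4)
  A <- 1
  pls <- nipals_pls_fit(world$X, world$y, A)
  lin <- pls_predict(pls, world$X)
  sig <- 1e4 * stats::var(as.numeric(pls$scores))
  hyb <- hybrid_fit(world$X, world$y, A, gamma = 1e7, sigma2 = sig)
  preds <- predict(hyb, world$X)
  expect_lt(max(abs(preds - lin)) / diff(range(world$y)), 0.01)
})

test_that("hyperparameter tuning is an argmin over the grid", {
  world <- small_world(n = 18, seed = 72)
  gg <- c(1, 100); sg <- c(1, 10)
  tun <- tune_hyperparameters(world$X, world$y, 1, gg, sg)
  expect_true(all(tun$press <= tun$table$press[is.finite(tun$table$press)]))
  expect_true(tun$gamma %in% gg && tun$sigma2 %in% sg)

  one <- tune_hyperparameters(world$X, world$y, 1, 10, 2.5)
  expect_equal(one$gamma, 10)
  expect_equal(one$sigma2, 2.5)
  expect_error(tune_hyperparameters(world$X, world$y, 1, numeric(0), 1),
               "empty grid")
})
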