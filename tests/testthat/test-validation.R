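test_that("press and r2_score match their definitions", {
  expect_equal(press(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(press(c(1, 2), c(2, 4)), 5)
  expect_error(press(1:3, 1:2), "length mismatch")

  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2_score(c(1, 2, 3), rep(2, 3)), 0)
  expect_lt(r2_score(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(r2_score(rep(1, 3), 1:3), "degenerate")

  set.seed(81)
  for (rep in 1:10) {
    y <- rnorm(12); p <- rnorm(12)
    n <- length(y)
    expect_equal(press(y, p), n * (sqrt(press(y, p) / n))^2)
  }
})

test_that("LOO cross-validation scores held-out predictions", {
  world <- small_world(n = 30, seed = 82, noise = 0, clean = TRUE)
  res <- loo_cv(world$X, world$y, 1, gamma = 1e5, sigma2 = 100)
  expect_gt(res$r_squared, 0.999)
  expect_identical(res$n, 30L)
  expect_equal(res$press, 30 * res$rmse^2, tolerance = 1e-12)

  # scrambled responses cannot be predicted out-of-sample
  set.seed(83)
  yp <- sample(world$y)
  bad <- loo_cv(world$X, yp, 1, gamma = 1e5, sigma2 = 100)
  expect_lt(bad$r_squared, 0.2)

  # minimal boundary case runs
  tiny <- small_world(n = 3, seed = 84)
  expect_silent(loo_cv(tiny$X, tiny$y, 1, gamma = 10, sigma2 = 10))
})

test_that("LMO holds out the stated fraction and is seed-stable", {
  world <- small_world(n = 25, seed = 85)
  res1 <- lmo_cv(world$X, world$y, 1, gamma = 1e4, sigma2 = 100,
                 fraction = 0.2, n_repeats = 6, seed = 42)
  res2 <- lmo_cv(world$X, world$y, 1, gamma = 1e4, sigma2 = 100,
                 fraction = 0.2, n_repeats = 6, seed = 42)
  expect_identical(res1, res2)
  # ceil(0.2 * 25) = 5 held out per round, pooled over 6 rounds
  expect_identical(res1$n, 30L)
  expect_gt(res1$r_squared, 0.99)
  expect_error(lmo_cv(world$X, world$y, 1, 10, 1, fraction = 1.2), "fraction")
})

test_that("training PRESS never exceeds LOO PRESS", {
  for (seed in c(86, 87)) {
    world <- small_world(n = 20, seed = seed, noise = 0.01)
    fit <- hybrid_fit(world$X, world$y, 1, gamma = 100, sigma2 = 10)
    p_train <- press(world$y, predict(fit, world$X))
    p_loo <- loo_cv(world$X, world$y, 1, gamma = 100, sigma2 = 10)$press
    expect_lte(p_train, p_loo)
  }
})

test_that("LV selection follows the parsimony rule", {
  world <- small_world(n = 25, seed = 88, noise = 1e-5, clean = TRUE)
  sel <- select_n_lv(world$X, world$y, 1:3, gamma = 1e5, sigma2 = 100)
  expect_identical(sel$chosen_lv, 1L)
  expect_identical(sel$table$n_lv, 1:3)
  sel2 <- select_n_lv(world$X, world$y, 2, gamma = 1e5, sigma2 = 100)
  expect_identical(sel2$chosen_lv, 2L)
})

test_that("external validation predicts without refitting", {
  world <- small_world(n = 30, seed = 89)
  fit <- hybrid_fit(world$X, world$y, 1, gamma = 1e4, sigma2 = 100)
  self <- external_validation(fit, world$X, world$y)
  expect_equal(self$r_squared, r2_score(world$y, predict(fit, world$X)))
  expect_error(external_validation(fit, world$X[0, , drop = FALSE],
                                   numeric(0)), "empty test set")
})

test_that("y-permutation separates structure from chance", {
  world <- small_world(n = 25, seed = 90, noise = 0.005)
  perm <- y_permutation_test(world$X, world$y, 1, gamma = 100, sigma2 = 100,
                             B = 20, seed = 1, include_cv = FALSE)
  expect_identical(perm$n_permutations, 20L)
  expect_lt(max(perm$permuted_r2), perm$observed_r2)
  expect_equal(perm$exceedance, 0)
  expect_gt(perm$observed_r2,
            quantile(perm$permuted_r2, 0.95, names = FALSE))

  # reproducibility under the seed
  perm2 <- y_permutation_test(world$X, world$y, 1, gamma = 100, sigma2 = 100,
                              B = 20, seed = 1, include_cv = FALSE)
  expect_identical(perm$permuted_r2, perm2$permuted_r2)

  # B = 1 boundary
  b1 <- y_permutation_test(world$X, world$y, 1, gamma = 100, sigma2 = 100,
                           B = 1, seed = 2, include_cv = FALSE)
  expect_length(b1$permuted_r2, 1)
})

test_that("pure-noise spectra are indistinguishable from their permutations", {
  set.seed(91)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- runif(30, 0.5, 25)
  perm <- y_permutation_test(X, y, 2, gamma = 1, sigma2 = 5, B = 20,
                             seed = 3, include_cv = FALSE)
  expect_gt(perm$exceedance, 0.05)
})

test_that("permutation CV metrics are recorded when requested", {
  world <- small_world(n = 12, seed = 92)
  perm <- y_permutation_test(world$X, world$y, 1, gamma = 10, sigma2 = 10,
                             B = 3, seed = 4, include_cv = TRUE,
                             lmo_repeats = 3)
  expect_true(all(is.finite(perm$permuted_q2_loo)))
  expect_true(all(is.finite(perm$permuted_q2_lmo)))
  expect_true(all(perm$permuted_q2_loo <= 1))
})

test_that("build_report assembles and serialises the full table", {
  world <- small_world(n = 20, seed = 93)
  idx <- kennard_stone(world$X, 15)
  Xc <- world$X[idx$calibration, ]; yc <- world$y[idx$calibration]
  Xt <- world$X[idx$test, ]; yt <- world$y[idx$test]
  rep_ <- build_report(Xc, yc, lv_range = 1:2, chosen_lv = 1,
                       gamma = 100, sigma2 = 10, X_test = Xt, y_test = yt,
                       lmo_repeats = 3, seed = 5)
  expect_setequal(names(rep_$per_lv), c("1", "2"))
  for (e in rep_$per_lv) {
    expect_named(e, c("prediction", "loo", "lmo"))
    for (ms in e) expect_named(ms, c("r_squared", "press", "rmse", "n"))
  }
  expect_error(build_report(Xc, yc, 1:2, chosen_lv = 5, gamma = 1,
                            sigma2 = 1), "chosen_lv")

  # JSON round trip is lossless
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$per_lv$`1`$loo$r_squared, rep_$per_lv$`1`$loo$r_squared)
  expect_equal(back$external$press, rep_$external$press)
  expect_identical(back$chosen_lv, 1L)

  # rendered table mirrors the r^2/PRESS x Prediction/LOO/LMO layout
  txt <- capture.output(print(rep_))
  expect_true(any(grepl("Prediction\\s+r\\^2", txt)))
  expect_true(any(grepl("CV \\(LOO\\)\\s+Q\\^2", txt)))
  expect_true(any(grepl("CV \\(LMO\\)\\s+Q\\^2", txt)))
  expect_identical(sum(grepl("^\\s+PRESS", txt)), 3L)
})
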