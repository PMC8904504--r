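test_that("spatial weights follow the adaptive bisquare and gaussian formulas", {
  coords <- cbind(c(0, 1, 2, 3, 10), c(0, 0, 0, 0, 0))
  w_bis <- spatial_weights(c(0, 0), coords, k = 4, type = "bisquare")
  # h = distance to 4th nearest = 3
  expect_equal(w_bis[1], 1) # d = 0
  expect_equal(w_bis[2], (1 - (1 / 3)^2)^2)
  expect_equal(w_bis[4], 0) # d = h has zero weight (compact support)
  expect_equal(w_bis[5], 0) # beyond h
  # d = h/2 gives (1 - 0.25)^2
  w_half <- spatial_weights(c(0, 0), cbind(c(0, 1, 2), 0), k = 3, "bisquare")
  expect_equal(w_half[2], (1 - 0.25)^2)

  w_gau <- spatial_weights(c(0, 0), coords, k = 4, type = "gaussian")
  expect_equal(w_gau[1], 1)
  expect_equal(w_gau[2], exp(-0.5 * (1 / 3)^2))
  expect_gt(w_gau[5], 0) # no compact support
  expect_error(spatial_weights(c(0, 0), coords, k = 6), "exceeds")
})

test_that("local WLS interpolates exact linear data and reduces to OLS under equal weights", {
  set.seed(1)
  x <- runif(30)
  y_exact <- 1 + 2 * x
  w <- runif(30, 0.5, 2)
  fit <- local_wls(x, y_exact, w, self = 1)
  expect_equal(c(fit$beta0, fit$beta1), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$fitted, y_exact[1], tolerance = 1e-10)

  y <- y_exact + rnorm(30, 0, 0.3)
  ols <- unname(coef(lm(y ~ x)))
  fit_eq <- local_wls(x, y, rep(1, 30), self = 5)
  expect_equal(c(fit_eq$beta0, fit_eq$beta1), ols, tolerance = 1e-8)

  # rank deficiency: constant predictor
  bad <- local_wls(rep(2, 30), y, w, self = 1)
  expect_false(bad$ok)
})

test_that("local WLS agrees with an explicit 2x2 normal-equation oracle", {
  set.seed(9)
  for (trial in 1:5) {
    inst <- random_gwr_instance(n = 30, seed = trial)
    w <- spatial_weights(inst$coords[7, ], inst$coords, k = 15, "bisquare")
    fit <- local_wls(inst$x, inst$y, w, self = 7)
    oracle <- brute_gwr(inst$x, inst$y, inst$coords, k = 15)[7, ]
    expect_equal(fit$beta0, oracle[["beta0"]], tolerance = 1e-8)
    expect_equal(fit$beta1, oracle[["beta1"]], tolerance = 1e-8)
    expect_equal(fit$hat, oracle[["hat"]], tolerance = 1e-8)
  }
})

test_that("the AICc formula evaluates correctly and penalises model complexity", {
  # n = 100, sigma_hat = 1, tr(S) = 5: the log term vanishes, leaving
  # 100 log(2 pi) + 100 * 105 / 93
  y <- rnorm(100)
  fitted <- y - 1 # RSS = 100 => sigma_hat = 1
  expect_equal(as.numeric(gwr_aicc(y, fitted, tr_s = 5)),
               100 * log(2 * pi) + 100 * 105 / 93,
               tolerance = 1e-10)
  # monotone penalty in tr(S) at fixed RSS
  vals <- vapply(c(2, 5, 10, 20), function(t) {
    as.numeric(gwr_aicc(y, fitted, t))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # infeasible when n <= tr(S) + 2
  expect_equal(gwr_aicc(y, fitted, tr_s = 98), Inf)
  # near-perfect fit floors sigma and flags
  flo <- gwr_aicc(y, y, tr_s = 5)
  expect_true(attr(flo, "floored"))
  expect_lt(as.numeric(flo), -1e3)
})

test_that("bandwidth selection responds to the spatial structure of the truth", {
  # constant coefficients: large k (global) beats the smallest k
  set.seed(21)
  hits <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- 120
    coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    x <- runif(n)
    y <- 1 + 2 * x + rnorm(n, 0, 0.1)
    sel <- select_bandwidth_aicc(x, y, coords)
    if (sel$k > n / 2) hits <- hits + 1
    a_small <- sel$evaluated$aicc[sel$evaluated$k == 10]
    expect_lte(sel$aicc, a_small)
  }
  expect_gte(hits, 5)

  # two spatial regimes of the slope: a local bandwidth wins
  hits_local <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    n <- 120
    coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    x <- runif(n)
    b1 <- ifelse(coords[, 1] < 5, 0, 3)
    y <- 1 + b1 * x + rnorm(n, 0, 0.1)
    sel <- select_bandwidth_aicc(x, y, coords)
    if (sel$k < n / 2) hits_local <- hits_local + 1
  }
  expect_gte(hits_local, 5)
})

test_that("an exact linear surface is interpolated everywhere by fit_gwr", {
  set.seed(4)
  vx <- matrix(runif(20 * 20, 0, 2), 20, 20)
  vy <- 3 + 0.5 * vx
  pair <- fake_intensity_pair(vx, vy)
  mask <- matrix(TRUE, 20, 20)
  fit <- fit_gwr(pair$epi, pair$imm, mask, k = 30)
  tab <- tidy(fit)
  expect_equal(nrow(tab), 400)
  expect_true(all(abs(tab$beta1 - 0.5) < 1e-6))
  expect_true(all(abs(tab$beta0 - 3) < 1e-6))
})

test_that("coefficients are invariant to grid-point ordering and hat trace is bounded", {
  inst <- random_gwr_instance(n = 80, seed = 3)
  sel <- select_bandwidth_aicc(inst$x, inst$y, inst$coords)
  nb <- gwrsig:::neighbour_structure(inst$coords)
  pass <- gwrsig:::gwr_pass(inst$x, inst$y, nb$ord, nb$dsort, sel$k, "bisquare")
  tr_s <- sum(pass$hat[pass$ok])
  expect_gte(tr_s, 2 - 1e-8)
  expect_lte(tr_s, 80)

  perm <- sample(80)
  nb_p <- gwrsig:::neighbour_structure(inst$coords[perm, ])
  pass_p <- gwrsig:::gwr_pass(inst$x[perm], inst$y[perm],
                              nb_p$ord, nb_p$dsort, sel$k, "bisquare")
  expect_equal(pass_p$beta1, pass$beta1[perm], tolerance = 1e-10)
  expect_equal(pass_p$beta0, pass$beta0[perm], tolerance = 1e-10)
})

test_that("gwr equals global OLS in the uniform-weight limit", {
  set.seed(12)
  n <- 60
  coords <- cbind(runif(n), runif(n))
  x <- runif(n)
  y <- 2 + 1.5 * x + rnorm(n, 0, 0.2)
  ols <- unname(coef(lm(y ~ x)))
  for (i in c(1, 17, 60)) {
    fit <- local_wls(x, y, rep(1, n), self = i)
    expect_equal(c(fit$beta0, fit$beta1), ols, tolerance = 1e-6)
  }
})

test_that("too-small masks and degenerate predictors are rejected or dropped", {
  vx <- matrix(runif(64), 8, 8)
  pair <- fake_intensity_pair(vx, 1 + vx)
  mask <- matrix(FALSE, 8, 8)
  mask[1:4, 1:4] <- TRUE # 16 < 30
  expect_error(fit_gwr(pair$epi, pair$imm, mask), "masked grid points")

  # constant predictor: every local fit is rank deficient
  pair2 <- fake_intensity_pair(matrix(1, 10, 10),
                               matrix(rnorm(100), 10, 10))
  fit2 <- fit_gwr(pair2$epi, pair2$imm, matrix(TRUE, 10, 10), k = 20)
  expect_equal(fit2$n_dropped, 100)
  expect_equal(nrow(tidy(fit2)), 0)
})
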