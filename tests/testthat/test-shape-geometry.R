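t512 <- seq(0, 1, length.out = 512)

test_that("the square-root transform lands on the unit sphere and inverts exactly", {
  # uniform density maps to the constant function 1
  psi_u <- to_srdf(rep(1, 512), t512)
  expect_equal(psi_u, rep(1, 512), tolerance = 1e-12)

  for (seed in 1:5) {
    f <- random_density(t512, seed)
    psi <- to_srdf(f, t512)
    w <- rep(t512[2], 512)
    w[c(1, 512)] <- w[c(1, 512)] / 2
    expect_equal(sum(w * psi^2), 1, tolerance = 1e-10)
    # round trip psi^2 -> f (up to the unit-norm renormalisation)
    expect_equal(psi^2 / trapz_int(t512, psi^2), f, tolerance = 1e-10)
  }
  expect_error(to_srdf(c(-1, rep(1, 511)), t512), "non-negative")
})

test_that("the Fisher-Rao distance matches quadrature, is a metric, and caps at pi/2", {
  expect_equal(
    fisher_rao_distance(to_srdf(rep(1, 512), t512),
                        to_srdf(rep(1, 512), t512), t512),
    0
  )
  # disjoint supports are orthogonal: d = pi/2
  f1 <- c(rep(2, 256), rep(0, 256)) + 1e-10
  f2 <- c(rep(0, 256), rep(2, 256)) + 1e-10
  d <- fisher_rao_distance(to_srdf(f1, t512), to_srdf(f2, t512), t512)
  expect_equal(d, pi / 2, tolerance = 1e-4)

  # fine-grid quadrature oracle on two beta densities
  t_fine <- seq(0, 1, length.out = 2048)
  fa <- beta_density(t_fine, 2, 4)
  fb <- beta_density(t_fine, 3, 3)
  d_pkg <- fisher_rao_distance(to_srdf(fa, t_fine), to_srdf(fb, t_fine),
                               t_fine)
  bc <- stats::integrate(function(u) sqrt(dbeta(u, 2, 4) * dbeta(u, 3, 3)),
                         0, 1, rel.tol = 1e-12)$value
  expect_equal(d_pkg, acos(bc), tolerance = 1e-6)

  # metric axioms on random triples
  set.seed(99)
  for (trial in 1:100) {
    fs <- lapply(sample(1e6, 3), function(s) random_density(t512, s))
    psis <- lapply(fs, to_srdf, t_grid = t512)
    d12 <- fisher_rao_distance(psis[[1]], psis[[2]], t512)
    d21 <- fisher_rao_distance(psis[[2]], psis[[1]], t512)
    d13 <- fisher_rao_distance(psis[[1]], psis[[3]], t512)
    d23 <- fisher_rao_distance(psis[[2]], psis[[3]], t512)
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d12, 0)
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("exp and log maps are mutually inverse with arc-length norms", {
  w <- rep(t512[2], 512)
  w[c(1, 512)] <- w[c(1, 512)] / 2
  base <- to_srdf(beta_density(t512, 3, 3), t512)
  expect_equal(log_map(base, base, t512), rep(0, 512))
  expect_equal(exp_map(base, rep(0, 512), t512), base)

  set.seed(17)
  max_err <- 0
  for (trial in 1:50) {
    psi <- to_srdf(random_density(t512, sample(1e6, 1)), t512)
    v <- log_map(base, psi, t512)
    # tangency and arc-length property
    expect_lt(abs(sum(w * v * base)), 1e-6)
    expect_equal(sqrt(sum(w * v^2)),
                 fisher_rao_distance(base, psi, t512), tolerance = 1e-10)
    back <- exp_map(base, v, t512)
    max_err <- max(max_err, max(abs(back - psi)))
  }
  expect_lt(max_err, 1e-8)
})

test_that("the Karcher mean of two densities is the geodesic midpoint", {
  f1 <- beta_density(t512, 2, 5)
  f2 <- beta_density(t512, 5, 2)
  psi1 <- to_srdf(f1, t512)
  psi2 <- to_srdf(f2, t512)
  mu <- karcher_mean(rbind(psi1, psi2), t512)
  d1 <- fisher_rao_distance(mu, psi1, t512)
  d2 <- fisher_rao_distance(mu, psi2, t512)
  expect_lt(abs(d1 - d2), 1e-5)
  expect_lt(abs(d1 + d2 - fisher_rao_distance(psi1, psi2, t512)), 1e-5)

  # identical inputs return the common density; singletons return themselves
  expect_equal(karcher_mean(rbind(psi1, psi1, psi1), t512), psi1,
               tolerance = 1e-8)
  expect_equal(karcher_mean(rbind(psi1), t512), psi1)

  # permutation invariance over a larger sample
  psis <- t(sapply(1:6, function(s) to_srdf(random_density(t512, s), t512)))
  mu_a <- karcher_mean(psis, t512)
  mu_b <- karcher_mean(psis[c(4, 2, 6, 1, 5, 3), ], t512)
  expect_equal(mu_a, mu_b, tolerance = 1e-6)
})

test_that("tangent PCA captures a single geodesic with one component and reconstructs", {
  base <- to_srdf(beta_density(t512, 4, 4), t512)
  dir_raw <- log_map(base, to_srdf(beta_density(t512, 2, 6), t512), t512)
  w <- rep(t512[2], 512)
  w[c(1, 512)] <- w[c(1, 512)] / 2
  dir <- dir_raw / sqrt(sum(w * dir_raw^2))
  psis <- t(sapply(seq(-0.3, 0.3, length.out = 10), function(s) {
    exp_map(base, s * dir, t512)
  }))
  model <- tangent_pca(psis, t512)
  expect_equal(model$k, 1L)
  expect_gte(model$var_explained[1], 0.9999)

  # reconstruction through the retained basis
  for (i in c(1, 5, 10)) {
    v_rec <- as.vector(model$vectors %*% model$scores[i, ])
    psi_rec <- exp_map(model$mean, v_rec, t512)
    expect_lt(fisher_rao_distance(psi_rec, psis[i, ], t512), 1e-3)
  }

  # total variance conservation: sum of eigenvalues = mean squared tangent norm
  v <- t(apply(psis, 1, function(p) log_map(model$mean, p, t512)))
  msq <- mean(apply(v, 1, function(vi) sum(w * vi^2)))
  expect_equal(sum(model$values), msq, tolerance = 1e-8)

  # degenerate sample: all identical
  same <- tangent_pca(rbind(base, base, base), t512)
  expect_equal(same$k, 0L)
  expect_true(same$degenerate)
})

test_that("projection reproduces training scores and zeroes the mean", {
  psis <- t(sapply(1:8, function(s) to_srdf(random_density(t512, s), t512)))
  model <- tangent_pca(psis, t512)
  for (i in c(2, 7)) {
    s_proj <- project_scores(psis[i, ]^2 / trapz_int(t512, psis[i, ]^2), model)
    expect_equal(s_proj, model$scores[i, seq_len(model$k)], tolerance = 1e-8)
  }
  mu_f <- model$mean^2 / trapz_int(t512, model$mean^2)
  expect_equal(project_scores(mu_f, model), rep(0, model$k),
               tolerance = 1e-8)
})

test_that("principal paths pass through the mean and step by sqrt-eigenvalue arcs", {
  psis <- t(sapply(1:9, function(s) to_srdf(random_density(t512, s + 50), t512)))
  model <- tangent_pca(psis, t512)
  path <- principal_path(model, 1)
  expect_equal(sort(unique(path$sd_multiple)), c(-2, -1, 0, 1, 2))
  mu_f <- model$mean^2 / trapz_int(t512, model$mean^2)
  f0 <- path$f[path$sd_multiple == 0]
  expect_equal(f0, mu_f, tolerance = 1e-8)
  # arc length from the mean grows as |s| sqrt(lambda_1)
  sdev <- sqrt(model$values[1])
  for (s in c(-2, -1, 1, 2)) {
    fs <- path$f[path$sd_multiple == s]
    d <- fisher_rao_distance(to_srdf(fs, t512), model$mean, t512)
    expect_equal(d, abs(s) * sdev, tolerance = 1e-6)
  }
  # opposite multiples differ when variance is positive
  expect_gt(max(abs(path$f[path$sd_multiple == 2] -
                      path$f[path$sd_multiple == -2])), 1e-4)
  expect_error(principal_path(model, model$k + 1), "exceeds")
})
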