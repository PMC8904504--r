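# Shared fixtures: everything is generated in code at test time.

# A tiny hand-written cell tibble covering two images.
toy_cells <- function() {
  tibble::tibble(
    subject_id = c(rep("s1", 7), rep("s2", 3)),
    image_id = c(rep("s1_img1", 7), rep("s2_img1", 3)),
    group = c(rep("g1", 7), rep("g2", 3)),
    x = c(10, 20, 30, 40, 15, 25, 35, 5, 50, 95),
    y = c(10, 20, 30, 40, 35, 25, 15, 5, 50, 95),
    phenotype = c(
      "epithelial", "epithelial", "epithelial", "immune", "immune",
      "immune", "other", "epithelial", "immune", "other"
    )
  )
}

# Small, fast simulation settings for unit tests (not the study conditions).
small_sim_params <- function(coupling = coupling_constant(1),
                             n_epithelial_mean = 60, ...) {
  group_sim_params(
    window = obs_window(0, 200, 0, 200),
    n_epithelial_mean = n_epithelial_mean,
    coupling = coupling,
    baseline_rate = 5e-4,
    ...
  )
}

# Synthetic intensity-grid pair carrying arbitrary value matrices, for GWR
# oracle instances decoupled from the kernel-smoothing stage.
fake_intensity_pair <- function(values_x, values_y, window = NULL) {
  n_x <- nrow(values_x)
  n_y <- ncol(values_x)
  if (is.null(window)) window <- obs_window(0, n_x, 0, n_y)
  grid <- make_grid(window, max(n_x, n_y))
  stopifnot(grid$n_x == n_x, grid$n_y == n_y)
  mk <- function(v, lab) {
    structure(
      list(values = v, edge = matrix(1, n_x, n_y), grid = grid,
           window = window, sigma = 1, label = lab, n_points = 1L),
      class = "intensity_grid"
    )
  }
  list(epi = mk(values_x, "epi"), imm = mk(values_y, "imm"))
}

# Independent brute-force GWR solver: per-location loops, explicit 2x2
# solve(); shares no code with the package's vectorised pass.
brute_gwr <- function(x, y, coords, k, type = "bisquare") {
  n <- length(x)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("beta0", "beta1", "fitted", "hat")))
  for (i in seq_len(n)) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
    h <- sort(d)[k]
    w <- if (type == "bisquare") {
      ww <- (1 - (d / h)^2)^2
      ww[d >= h] <- 0
      ww
    } else {
      exp(-0.5 * (d / h)^2)
    }
    xtx <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
    xty <- c(sum(w * y), sum(w * x * y))
    beta <- tryCatch(solve(xtx, xty), error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(beta))) next
    xi <- c(1, x[i])
    out[i, ] <- c(
      beta[1], beta[2], sum(xi * beta),
      w[i] * drop(t(xi) %*% solve(xtx) %*% xi)
    )
  }
  out
}

# Independent AICc evaluation from a brute-force fit at bandwidth k.
brute_aicc <- function(x, y, coords, k, type = "bisquare") {
  fit <- brute_gwr(x, y, coords, k, type)
  ok <- is.finite(fit[, "fitted"])
  n <- sum(ok)
  tr_s <- sum(fit[ok, "hat"])
  if (n <= tr_s + 2) return(Inf)
  sigma <- sqrt(sum((y[ok] - fit[ok, "fitted"])^2) / n)
  sigma <- max(sigma, 1e-12)
  2 * n * log(sigma) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
}

# Random masked-grid GWR instance: spatially varying truth plus noise.
random_gwr_instance <- function(n = 200, seed = 1) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  x <- runif(n, 0, 2)
  beta1_true <- 1 + 0.3 * coords[, 1]
  y <- 0.5 + beta1_true * x + rnorm(n, 0, 0.2)
  list(x = x, y = y, coords = coords)
}

# Densities on [0, 1] built from scaled-beta mixtures, as a stand-in
# signature cohort independent of the GWR stage.
beta_density <- function(t_grid, shape1, shape2) {
  f <- stats::dbeta(t_grid, shape1, shape2)
  f <- pmax(f, 1e-10)
  m <- length(t_grid)
  w <- rep(t_grid[2] - t_grid[1], m)
  w[c(1, m)] <- w[c(1, m)] / 2
  f / sum(w * f)
}

random_density <- function(t_grid, seed) {
  set.seed(seed)
  a1 <- runif(1, 2, 8)
  b1 <- runif(1, 2, 8)
  a2 <- runif(1, 2, 8)
  b2 <- runif(1, 2, 8)
  p <- runif(1, 0.2, 0.8)
  f <- p * beta_density(t_grid, a1, b1) + (1 - p) * beta_density(t_grid, a2, b2)
  m <- length(t_grid)
  w <- rep(t_grid[2] - t_grid[1], m)
  w[c(1, m)] <- w[c(1, m)] / 2
  f / sum(w * f)
}

# A signature_set assembled directly from chosen densities (bypasses GWR).
make_signature_set <- function(f_matrix, groups, t_grid, level = "image") {
  structure(
    list(
      f = f_matrix, t = t_grid,
      meta = tibble::tibble(
        owner = sprintf("o%02d", seq_len(nrow(f_matrix))),
        group = groups
      ),
      scaling = structure(list(global_min = 0, global_max = 1),
                          class = "scaling_spec"),
      level = level, bw = NULL
    ),
    class = "signature_set"
  )
}

# Cohort signatures where each owner's density is a KDE of draws from a
# group-specific distribution; fast stand-in for pipeline output.
simulated_signature_cohort <- function(n_per_group, means, sds, seed,
                                       m = 512, n_values = 400) {
  set.seed(seed)
  groups <- character(0)
  rows <- list()
  scaling <- structure(list(global_min = 0, global_max = 1),
                       class = "scaling_spec")
  idx <- 1
  for (g in names(means)) {
    for (i in seq_len(n_per_group)) {
      vals <- pmin(1, pmax(0, stats::rnorm(n_values, means[[g]], sds[[g]])))
      rows[[idx]] <- coefficient_density(vals, scaling, m = m)$f
      groups <- c(groups, g)
      idx <- idx + 1
    }
  }
  make_signature_set(do.call(rbind, rows), groups,
                     seq(0, 1, length.out = m))
}

# trapezoid integral, independent of package internals
trapz_int <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# indices of strict interior local maxima, returned as x positions
local_maxima <- function(x, y) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  x[i]
}
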