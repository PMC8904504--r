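#' Build an evaluation grid over an observation window
#'
#' The grid is a lattice of cell centers covering the window exactly, with
#' the number of cells along each axis proportional to the window dimensions:
#' the longer side receives `n_max` cells and the other side is rounded so
#' the grid aspect ratio matches the window aspect ratio to within one cell.
#'
#' @param window An [obs_window()].
#' @param n_max Number of grid cells along the longer window side
#'   (default 128).
#' @return An object of class `grid_spec`: list with `n_x`, `n_y`, center
#'   coordinate vectors `x`, `y`, spacings `dx`, `dy`, and `cell_area`.
#' @export
make_grid <- function(window, n_max = 128) {
  stopifnot(inherits(window, "obs_window"))
  wx <- window$x_max - window$x_min
  wy <- window$y_max - window$y_min
  if (wx >= wy) {
    n_x <- as.integer(n_max)
    n_y <- max(2L, as.integer(round(n_max * wy / wx)))
  } else {
    n_y <- as.integer(n_max)
    n_x <- max(2L, as.integer(round(n_max * wx / wy)))
  }
  if (n_x < 2 || n_y < 2) {
    stop("resolution yields a grid smaller than 2 x 2", call. = FALSE)
  }
  dx <- wx / n_x
  dy <- wy / n_y
  structure(
    list(
      n_x = n_x, n_y = n_y,
      x = window$x_min + (seq_len(n_x) - 0.5) * dx,
      y = window$y_min + (seq_len(n_y) - 0.5) * dy,
      dx = dx, dy = dy, cell_area = dx * dy
    ),
    class = "grid_spec"
  )
}

#' Edge-correction factor for a Gaussian kernel in a rectangular window
#'
#' Returns `e(u) = 1 / integral_W k(v - u) dv`, the reciprocal of the
#' Gaussian kernel mass retained inside the window. For an axis-aligned
#' rectangle the integral factorises into a product of two one-dimensional
#' normal CDF differences, so the factor is computed in closed form.
#' `e(u) >= 1` everywhere, tends to 1 deep in the interior, and equals 4 at
#' a corner of a large window (a quarter of the kernel mass retained).
#'
#' @param ux,uy Coordinates of evaluation points (vectors of equal length).
#' @param window An [obs_window()].
#' @param sigma Gaussian kernel standard deviation.
#' @return Vector of edge factors `e(u)`.
#' @export
edge_correction_factor <- function(ux, uy, window, sigma) {
  stopifnot(sigma > 0)
  inside <- ux >= window$x_min & ux <= window$x_max &
    uy >= window$y_min & uy <= window$y_max
  if (!all(inside)) {
    stop("evaluation point outside the observation window", call. = FALSE)
  }
  mass_x <- stats::pnorm(window$x_max, ux, sigma) -
    stats::pnorm(window$x_min, ux, sigma)
  mass_y <- stats::pnorm(window$y_max, uy, sigma) -
    stats::pnorm(window$y_min, uy, sigma)
  1 / (mass_x * mass_y)
}

#' Edge-corrected Gaussian kernel intensity on a grid
#'
#' Estimates the point-process intensity
#' `lambda(u) = e(u) * sum_i k(x_i - u) w_i` at every grid center, where `k`
#' is the isotropic bivariate Gaussian density with standard deviation
#' `sigma`, `w_i` are per-point weights (default 1), and `e(u)` the
#' closed-form rectangular edge correction of [edge_correction_factor()].
#' The separable Gaussian lets the full grid be computed as a product of two
#' one-dimensional kernel matrices.
#'
#' @param points Tibble/data frame with columns `x`, `y` (cells of one
#'   phenotype); at least one point, all inside the window.
#' @param window An [obs_window()].
#' @param grid A [make_grid()] spec.
#' @param sigma Kernel standard deviation; default [default_sigma()].
#' @param weights Per-point positive weights, recycled scalar allowed.
#' @param label Phenotype label carried on the result.
#' @return An object of class `intensity_grid`: list with matrices `values`
#'   (`n_x` by `n_y`, points per unit area) and `edge` (edge factors), plus
#'   `grid`, `window`, `sigma`, `label`, `n_points`.
#' @export
kernel_intensity <- function(points, window, grid, sigma = default_sigma(window),
                             weights = 1, label = "") {
  if (nrow(points) == 0) {
    stop(
      "kernel_intensity needs at least one point; ",
      "apply the inclusion criteria before estimating intensities",
      call. = FALSE
    )
  }
  inside <- points$x >= window$x_min & points$x <= window$x_max &
    points$y >= window$y_min & points$y <= window$y_max
  if (!all(inside)) {
    stop("point(s) outside the observation window", call. = FALSE)
  }
  w <- rep_len(weights, nrow(points))
  stopifnot(all(w > 0), sigma > 0)
  # separable Gaussian: lambda[j, k] = sum_i w_i phi(gx_j - x_i) phi(gy_k - y_i)
  kx <- stats::dnorm(outer(grid$x, points$x, "-"), sd = sigma) # n_x x n
  ky <- stats::dnorm(outer(grid$y, points$y, "-"), sd = sigma) # n_y x n
  raw <- kx %*% (w * t(ky)) # n_x x n_y
  uu <- expand.grid(x = grid$x, y = grid$y)
  edge <- matrix(
    edge_correction_factor(uu$x, uu$y, window, sigma),
    nrow = grid$n_x, ncol = grid$n_y
  )
  structure(
    list(
      values = edge * raw, edge = edge, grid = grid, window = window,
      sigma = sigma, label = label, n_points = nrow(points)
    ),
    class = "intensity_grid"
  )
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf(
    "<intensity_grid %s: %d x %d grid, %d points, sigma = %.3g>\n",
    x$label, x$grid$n_x, x$grid$n_y, x$n_points, x$sigma
  ))
  invisible(x)
}

#' @method as_tibble intensity_grid
#' @export
as_tibble.intensity_grid <- function(x, ...) {
  uu <- expand.grid(x = x$grid$x, y = x$grid$y)
  tibble::tibble(
    x = uu$x, y = uu$y,
    lambda = as.vector(x$values),
    edge_factor = as.vector(x$edge)
  )
}

#' Mask of grid points with epithelial intensity above a threshold
#'
#' The GWR model is fitted only where the epithelial (predictor) intensity
#' exceeds a small threshold `tau`, to avoid ill-conditioned local fits in
#' empty regions; the same mask is then used to extract the immune
#' (response) intensity.
#'
#' @param epi An `intensity_grid` for the epithelial phenotype.
#' @param tau Non-negative intensity threshold.
#' @param n_min Minimum masked grid points expected downstream; fewer
#'   triggers a warning here (and an error at the GWR stage).
#' @return Logical matrix, `TRUE` where `lambda_epi(u) > tau`.
#' @export
threshold_mask <- function(epi, tau, n_min = 30) {
  stopifnot(inherits(epi, "intensity_grid"), tau >= 0)
  mask <- epi$values > tau
  if (sum(mask) < n_min) {
    warning(
      "threshold mask keeps only ", sum(mask), " grid points (tau = ",
      format(tau), "); the GWR stage requires at least ", n_min,
      call. = FALSE
    )
  }
  mask
}

#' Cohort-level default intensity threshold
#'
#' The default `tau` is a small quantile (1st percentile) of the pooled
#' epithelial intensity values across all images of the cohort — "reasonably
#' small after observing the spread" of the intensities — and can be
#' overridden by an absolute value in the pipeline configuration.
#'
#' @param epi_list List of epithelial `intensity_grid`s (one per image).
#' @param prob Quantile level (default 0.01).
#' @return A scalar threshold.
#' @export
cohort_tau <- function(epi_list, prob = 0.01) {
  pooled <- unlist(lapply(epi_list, function(g) as.vector(g$values)))
  unname(stats::quantile(pooled, prob))
}
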