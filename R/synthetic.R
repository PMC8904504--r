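#' Coupling-field constructors
#'
#' A coupling field `b(u)` gives the local strength with which the immune
#' intensity follows the (smoothed) epithelial intensity:
#' `lambda_imm(u) = max(0, a + b(u) * lambda_epi(u))`. Three shapes are
#' provided: spatially constant, a linear gradient along one axis, and a
#' patchwise (checkerboard-style) field defined by a matrix of values over
#' an `n_px` by `n_py` partition of the window.
#'
#' @param b Constant coupling value.
#' @param b_min,b_max Gradient endpoints (at the low/high edge of `axis`).
#' @param axis `"x"` or `"y"` for the gradient direction.
#' @param values Numeric matrix of patch values, `n_px` rows (x-direction)
#'   by `n_py` columns (y-direction).
#' @return An object of class `coupling_field`: a function `(x, y, window)`
#'   returning `b` at each location, with a `spec` attribute.
#' @export
coupling_constant <- function(b) {
  new_coupling(function(x, y, window) rep_len(b, length(x)),
               list(type = "constant", b = b))
}

#' @rdname coupling_constant
#' @export
coupling_gradient <- function(b_min, b_max, axis = c("x", "y")) {
  axis <- match.arg(axis)
  new_coupling(function(x, y, window) {
    if (axis == "x") {
      frac <- (x - window$x_min) / (window$x_max - window$x_min)
    } else {
      frac <- (y - window$y_min) / (window$y_max - window$y_min)
    }
    b_min + (b_max - b_min) * frac
  }, list(type = "gradient", b_min = b_min, b_max = b_max, axis = axis))
}

#' @rdname coupling_constant
#' @export
coupling_patchwise <- function(values) {
  values <- as.matrix(values)
  new_coupling(function(x, y, window) {
    n_px <- nrow(values)
    n_py <- ncol(values)
    ix <- pmin(
      n_px,
      1 + floor(n_px * (x - window$x_min) / (window$x_max - window$x_min))
    )
    iy <- pmin(
      n_py,
      1 + floor(n_py * (y - window$y_min) / (window$y_max - window$y_min))
    )
    values[cbind(ix, iy)]
  }, list(type = "patchwise", values = values))
}

new_coupling <- function(fn, spec) {
  structure(fn, spec = spec, class = c("coupling_field", "function"))
}

#' Simulation parameters for one disease group
#'
#' Defaults emulate a 0.6 mm tissue-microarray core imaged in microns: a
#' 600 x 600 window, a few hundred epithelial cells, and an immune baseline
#' rate giving on the order of 50-100 baseline immune cells per image.
#'
#' @param window Observation window (default `[0, 600]^2` microns).
#' @param n_epithelial_mean Expected epithelial cell count (default 300).
#' @param epithelial_process `"poisson"` (homogeneous) or `"thomas"`
#'   (Thomas cluster process).
#' @param cluster_params For `"thomas"`: list with `offspring_mean` and
#'   `cluster_sd`; the parent rate is derived so the expected total count is
#'   `n_epithelial_mean`.
#' @param coupling A `coupling_field` (default `coupling_constant(1)`).
#' @param baseline_rate Baseline immune intensity `a >= 0` per unit area
#'   (default 2e-4, i.e. ~72 baseline immune cells in the default window).
#' @param noise_sd Standard deviation of a per-image Gaussian random effect
#'   added to the coupling field (between-image heterogeneity; default 0).
#' @param sigma Smoothing bandwidth of the latent epithelial field the
#'   immune process conditions on; default a quarter of [default_sigma()]
#'   of the window. The latent field is deliberately finer than the
#'   analysis-side intensity kernel: the analysis smooths the immune sample
#'   once more, so a latent field at the analysis bandwidth would be
#'   smoothed twice in the response and attenuate the recoverable slope,
#'   whereas a finer latent field leaves the predictor-response slope
#'   essentially equal to the coupling `b`.
#' @return An object of class `group_sim_params`.
#' @export
group_sim_params <- function(window = obs_window(0, 600, 0, 600),
                             n_epithelial_mean = 300,
                             epithelial_process = c("poisson", "thomas"),
                             cluster_params = list(offspring_mean = 20,
                                                   cluster_sd = 25),
                             coupling = coupling_constant(1),
                             baseline_rate = 2e-4,
                             noise_sd = 0,
                             sigma = default_sigma(window) / 4) {
  epithelial_process <- match.arg(epithelial_process)
  stopifnot(
    inherits(window, "obs_window"), n_epithelial_mean >= 0,
    inherits(coupling, "coupling_field"), baseline_rate >= 0, noise_sd >= 0,
    sigma > 0
  )
  structure(
    list(
      window = window, n_epithelial_mean = n_epithelial_mean,
      epithelial_process = epithelial_process, cluster_params = cluster_params,
      coupling = coupling, baseline_rate = baseline_rate,
      noise_sd = noise_sd, sigma = sigma
    ),
    class = "group_sim_params"
  )
}

# Deterministic 32-bit seed derived from a master seed and string ids,
# stable across platforms and iteration order.
stable_seed <- function(master, ...) {
  ids <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(ids)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate one two-type cell image
#'
#' Epithelial points are drawn from the configured process (homogeneous
#' Poisson or Thomas cluster). The immune pattern is an inhomogeneous
#' Poisson process with rate `max(0, a + b(u) * lambda_epi(u))`, where
#' `lambda_epi` is the smoothed (edge-corrected Gaussian-kernel) field of
#' the realised epithelial points, so the analysis-side GWR generative
#' assumption — immune intensity locally linear in epithelial intensity —
#' holds by construction and coefficient recovery is well posed. Sampling
#' is by exact thinning of a homogeneous proposal at (a safely inflated
#' estimate of) the rate supremum.
#'
#' @param params A [group_sim_params()].
#' @param seed Integer seed; identical `(params, seed)` give identical
#'   tables.
#' @param subject_id,image_id,group Identifier strings stamped on the rows.
#' @return A cell tibble in canonical layout (possibly zero rows).
#' @export
simulate_image <- function(params, seed, subject_id = "S1",
                           image_id = "S1_img1", group = "sim") {
  stopifnot(inherits(params, "group_sim_params"))
  win <- params$window
  with_seed(seed, {
    epi <- simulate_epithelial(params)
    # image-level random effect on the coupling field, drawn once per image
    offset <- if (params$noise_sd > 0) stats::rnorm(1, 0, params$noise_sd) else 0
    rate_fn <- function(x, y) {
      lam <- if (nrow(epi) > 0) {
        smoothed_field(x, y, epi, win, params$sigma)
      } else {
        0
      }
      pmax(0, params$baseline_rate +
             (params$coupling(x, y, win) + offset) * lam)
    }
    imm <- sample_inhomogeneous(rate_fn, win, rate_sup(params, epi, offset))
    cells <- rbind(
      if (nrow(epi) > 0) cbind(epi, phenotype = "epithelial"),
      if (nrow(imm) > 0) cbind(imm, phenotype = "immune")
    )
    if (is.null(cells) || nrow(cells) == 0) {
      return(tibble::tibble(
        subject_id = character(), image_id = character(), group = character(),
        x = numeric(), y = numeric(), phenotype = character()
      ))
    }
    tibble::tibble(
      subject_id = subject_id, image_id = image_id, group = group,
      x = cells$x, y = cells$y, phenotype = cells$phenotype
    )
  })
}

simulate_epithelial <- function(params) {
  win <- params$window
  if (params$epithelial_process == "poisson") {
    n <- stats::rpois(1, params$n_epithelial_mean)
    return(data.frame(
      x = stats::runif(n, win$x_min, win$x_max),
      y = stats::runif(n, win$y_min, win$y_max)
    ))
  }
  mu <- params$cluster_params$offspring_mean
  sd <- params$cluster_params$cluster_sd
  pad <- 4 * sd
  area_ext <- (win$x_max - win$x_min + 2 * pad) *
    (win$y_max - win$y_min + 2 * pad)
  parent_rate <- params$n_epithelial_mean / (mu * window_area(win))
  n_parents <- stats::rpois(1, parent_rate * area_ext)
  if (n_parents == 0) return(data.frame(x = numeric(), y = numeric()))
  px <- stats::runif(n_parents, win$x_min - pad, win$x_max + pad)
  py <- stats::runif(n_parents, win$y_min - pad, win$y_max + pad)
  n_off <- stats::rpois(n_parents, mu)
  cx <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sd)
  cy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sd)
  keep <- cx >= win$x_min & cx <= win$x_max & cy >= win$y_min & cy <= win$y_max
  data.frame(x = cx[keep], y = cy[keep])
}

# Edge-corrected Gaussian kernel field of a realised point set, evaluated
# exactly at arbitrary locations (no grid interpolation).
smoothed_field <- function(x, y, pts, window, sigma) {
  e <- edge_correction_factor(x, y, window, sigma)
  kx <- stats::dnorm(outer(x, pts$x, "-"), sd = sigma)
  ky <- stats::dnorm(outer(y, pts$y, "-"), sd = sigma)
  e * rowSums(kx * ky)
}

# Inflated estimate of the supremum of the immune rate field, computed on a
# fine grid with the separable form of the Gaussian kernel sum.
rate_sup <- function(params, epi, offset, sup_grid = 128) {
  win <- params$window
  if (nrow(epi) == 0) return(params$baseline_rate * 1.5)
  gx <- seq(win$x_min, win$x_max, length.out = sup_grid)
  gy <- seq(win$y_min, win$y_max, length.out = sup_grid)
  kx <- stats::dnorm(outer(gx, epi$x, "-"), sd = params$sigma)
  ky <- stats::dnorm(outer(gy, epi$y, "-"), sd = params$sigma)
  inv_ex <- 1 / (stats::pnorm(win$x_max, gx, params$sigma) -
                   stats::pnorm(win$x_min, gx, params$sigma))
  inv_ey <- 1 / (stats::pnorm(win$y_max, gy, params$sigma) -
                   stats::pnorm(win$y_min, gy, params$sigma))
  lam <- outer(inv_ex, inv_ey) * (kx %*% t(ky))
  gg <- expand.grid(x = gx, y = gy)
  bb <- matrix(params$coupling(gg$x, gg$y, win) + offset, sup_grid, sup_grid)
  max(pmax(0, params$baseline_rate + bb * lam)) * 1.5
}

# Exact thinning of a homogeneous proposal at an upper bound of the rate.
sample_inhomogeneous <- function(rate_fn, window, lam_max) {
  if (!is.finite(lam_max) || lam_max <= 0) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  n_prop <- stats::rpois(1, lam_max * window_area(window))
  if (n_prop == 0) return(data.frame(x = numeric(), y = numeric()))
  px <- stats::runif(n_prop, window$x_min, window$x_max)
  py <- stats::runif(n_prop, window$y_min, window$y_max)
  accept <- stats::runif(n_prop) < pmin(1, rate_fn(px, py) / lam_max)
  data.frame(x = px[accept], y = py[accept])
}

#' Simulate a multi-group cohort
#'
#' Subject and image identifiers encode group, subject index and image
#' index; every image gets an independent child seed derived by a stable
#' hash of the master seed and its identifiers, so the output is
#' reproducible and independent of iteration order.
#'
#' @param group_params Named list of [group_sim_params()], one per group.
#' @param n_subjects Named integer vector (same names) of subjects per
#'   group.
#' @param images_per_subject Images per subject (default 2).
#' @param seed Master integer seed.
#' @return A cohort cell tibble (all groups, subjects and images stacked).
#' @export
simulate_cohort <- function(group_params, n_subjects, images_per_subject = 2,
                            seed = 1) {
  stopifnot(
    length(group_params) >= 1,
    all(names(n_subjects) %in% names(group_params)),
    all(n_subjects >= 1), images_per_subject >= 1
  )
  rows <- list()
  for (g in names(group_params)) {
    for (s in seq_len(n_subjects[[g]])) {
      sid <- sprintf("%s_s%02d", g, s)
      for (i in seq_len(images_per_subject)) {
        iid <- sprintf("%s_img%d", sid, i)
        rows[[iid]] <- simulate_image(
          group_params[[g]],
          seed = stable_seed(seed, g, sid, iid),
          subject_id = sid, image_id = iid, group = g
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
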