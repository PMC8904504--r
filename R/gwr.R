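#' Adaptive spatial weights at a location
#'
#' The adaptive bandwidth at `u` is the distance to the k-th nearest of the
#' fit locations (including `u` itself when it is one of them). Bisquare
#' weights `(1 - (d/h)^2)^2` vanish at and beyond `h` (compact support);
#' Gaussian weights `exp(-d^2 / (2 h^2))` never vanish. The weight at `u`
#' itself (distance 0) is 1 for both.
#'
#' @param u Numeric length-2 location `(x, y)`.
#' @param coords Two-column matrix of fit locations.
#' @param k Adaptive neighbour count, `k <= nrow(coords)`.
#' @param type `"bisquare"` (default) or `"gaussian"`.
#' @return Weight vector over the rows of `coords`.
#' @export
spatial_weights <- function(u, coords, k, type = c("bisquare", "gaussian")) {
  type <- match.arg(type)
  n <- nrow(coords)
  if (k > n) stop("k exceeds the number of locations", call. = FALSE)
  d <- sqrt((coords[, 1] - u[1])^2 + (coords[, 2] - u[2])^2)
  h <- sort(d, partial = k)[k]
  weight_from_dist(d, h, type)
}

weight_from_dist <- function(d, h, type) {
  if (type == "bisquare") {
    w <- (1 - (d / h)^2)^2
    w[d >= h] <- 0
    w
  } else {
    exp(-0.5 * (d / h)^2)
  }
}

#' Local weighted least squares of one response on one predictor
#'
#' Solves the 2-parameter weighted normal equations at a single fit location
#' and returns the local intercept and slope, the fitted value for the
#' location's own observation, and the corresponding hat-matrix diagonal
#' element (leverage of the location's own observation under its local fit).
#'
#' @param x Predictor values at all fit locations.
#' @param y Response values at all fit locations.
#' @param weights Spatial weights (from [spatial_weights()]).
#' @param self Index of the fit location's own observation.
#' @return List with `beta0`, `beta1`, `fitted`, `hat` (or all `NA` with
#'   `ok = FALSE` when the weighted design is rank deficient).
#' @export
local_wls <- function(x, y, weights, self) {
  use <- weights > 0
  if (sum(use) < 3) {
    return(list(beta0 = NA_real_, beta1 = NA_real_, fitted = NA_real_,
                hat = NA_real_, ok = FALSE))
  }
  s0 <- sum(weights)
  sx <- sum(weights * x)
  sxx <- sum(weights * x^2)
  sy <- sum(weights * y)
  sxy <- sum(weights * x * y)
  det <- s0 * sxx - sx^2
  if (!is.finite(det) || det <= .Machine$double.eps * s0 * max(sxx, 1)) {
    return(list(beta0 = NA_real_, beta1 = NA_real_, fitted = NA_real_,
                hat = NA_real_, ok = FALSE))
  }
  beta1 <- (s0 * sxy - sx * sy) / det
  beta0 <- (sxx * sy - sx * sxy) / det
  xs <- x[self]
  list(
    beta0 = beta0, beta1 = beta1,
    fitted = beta0 + beta1 * xs,
    hat = weights[self] * (sxx - 2 * xs * sx + xs^2 * s0) / det,
    ok = TRUE
  )
}

# Vectorised GWR pass at a fixed adaptive k over precomputed neighbour
# structure. ord/dsort are n x n matrices of neighbour indices / sorted
# distances per row (self first, distance 0).
gwr_pass <- function(x, y, ord, dsort, k, type) {
  n <- length(x)
  idx <- ord[, seq_len(k), drop = FALSE]
  d <- dsort[, seq_len(k), drop = FALSE]
  h <- dsort[, k]
  w <- if (type == "bisquare") {
    wm <- (1 - (d / h)^2)^2
    wm[d >= h] <- 0
    wm
  } else {
    exp(-0.5 * (d / h)^2)
  }
  xm <- matrix(x[idx], n, k)
  ym <- matrix(y[idx], n, k)
  s0 <- rowSums(w)
  sx <- rowSums(w * xm)
  sxx <- rowSums(w * xm^2)
  sy <- rowSums(w * ym)
  sxy <- rowSums(w * xm * ym)
  det <- s0 * sxx - sx^2
  ok <- is.finite(det) & det > .Machine$double.eps * s0 * pmax(sxx, 1) &
    rowSums(w > 0) >= 3
  beta1 <- (s0 * sxy - sx * sy) / det
  beta0 <- (sxx * sy - sx * sxy) / det
  fitted <- beta0 + beta1 * x
  hat <- w[, 1] * (sxx - 2 * x * sx + x^2 * s0) / det
  beta0[!ok] <- beta1[!ok] <- fitted[!ok] <- hat[!ok] <- NA_real_
  list(beta0 = beta0, beta1 = beta1, fitted = fitted, hat = hat, ok = ok)
}

#' Corrected Akaike information criterion for a GWR fit
#'
#' The small-sample ("second order") AIC used to score GWR bandwidths:
#' `AICc = 2 n log(sigma_hat) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))`
#' with `sigma_hat^2 = RSS / n` and `tr(S)` the trace of the hat matrix (the
#' effective number of parameters). Infeasible when `n <= tr(S) + 2`.
#'
#' @param y Observed response.
#' @param fitted Fitted values (same length; `NA` pairs are dropped).
#' @param tr_s Hat-matrix trace.
#' @return The AICc value, or `Inf` when infeasible. A near-perfect fit has
#'   `sigma_hat` floored at 1e-12 (attribute `floored`).
#' @export
gwr_aicc <- function(y, fitted, tr_s) {
  keep <- is.finite(fitted)
  y <- y[keep]
  fitted <- fitted[keep]
  n <- length(y)
  if (!is.finite(tr_s) || n <= tr_s + 2) {
    return(Inf)
  }
  sigma <- sqrt(sum((y - fitted)^2) / n)
  floored <- sigma < 1e-12
  if (floored) sigma <- 1e-12
  out <- 2 * n * log(sigma) + n * log(2 * pi) +
    n * (n + tr_s) / (n - 2 - tr_s)
  attr(out, "floored") <- floored
  out
}

aicc_for_k <- function(x, y, ord, dsort, k, type) {
  pass <- gwr_pass(x, y, ord, dsort, k, type)
  tr_s <- sum(pass$hat[pass$ok])
  gwr_aicc(y[pass$ok], pass$fitted[pass$ok], tr_s)
}

#' Select the adaptive GWR bandwidth by AICc minimisation
#'
#' Chooses the neighbour count `k*` minimising the corrected AIC of the full
#' GWR fit. For `n <= 500` fit locations the search is exhaustive over all
#' integer `k` in `[k_min, n]`; for larger problems a golden-section search
#' on the integers (with memoisation) is used.
#'
#' @param x,y Predictor and response at the masked grid points.
#' @param coords Two-column coordinate matrix of the masked grid points.
#' @param type Spatial kernel, `"bisquare"` (default) or `"gaussian"`.
#' @param k_min Smallest admissible neighbour count (default 10).
#' @param exhaustive_max Largest `n` for which the search is exhaustive.
#' @param nb Precomputed neighbour structure (internal reuse).
#' @return List with `k` (the minimiser), `aicc` (its score), and
#'   `evaluated` (tibble of candidate `k` and scores).
#' @export
select_bandwidth_aicc <- function(x, y, coords,
                                  type = c("bisquare", "gaussian"),
                                  k_min = 10, exhaustive_max = 500,
                                  nb = NULL) {
  type <- match.arg(type)
  n <- length(x)
  if (k_min > n) {
    stop("fewer masked grid points than k_min; lower tau or coarsen the grid",
         call. = FALSE)
  }
  if (is.null(nb)) nb <- neighbour_structure(coords)
  cache <- new.env(parent = emptyenv())
  score <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- as.numeric(aicc_for_k(x, y, nb$ord, nb$dsort, k, type))
    cache[[key]] <- val
    val
  }
  if (n <= exhaustive_max) {
    ks <- k_min:n
    vals <- vapply(ks, score, numeric(1))
  } else {
    golden_int_search(score, k_min, n)
    ks <- as.integer(ls(cache))
    vals <- vapply(as.character(ks), function(key) cache[[key]], numeric(1))
    o <- order(ks)
    ks <- ks[o]
    vals <- vals[o]
  }
  if (all(!is.finite(vals))) {
    stop(
      "no feasible bandwidth: every candidate k gives n <= tr(S) + 2; ",
      "lower tau or coarsen the grid",
      call. = FALSE
    )
  }
  best <- which.min(vals)
  list(
    k = ks[best], aicc = vals[best],
    evaluated = tibble::tibble(k = ks, aicc = vals)
  )
}

neighbour_structure <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  ord <- t(apply(d, 1, order))
  dsort <- matrix(d[cbind(rep(seq_len(nrow(d)), ncol(d)), as.vector(ord))],
                  nrow(d), ncol(d))
  list(ord = ord, dsort = dsort)
}

# Golden-section minimisation over the integers of [lo, hi]; assumes a
# roughly unimodal score. Evaluations are memoised by the caller's closure.
golden_int_search <- function(score, lo, hi) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo
  b <- hi
  x1 <- round(b - phi * (b - a))
  x2 <- round(a + phi * (b - a))
  while (b - a > 2) {
    if (score(x1) <= score(x2)) {
      b <- x2
      x2 <- x1
      x1 <- round(b - phi * (b - a))
      if (x1 == x2) x1 <- max(a, x1 - 1)
    } else {
      a <- x1
      x1 <- x2
      x2 <- round(a + phi * (b - a))
      if (x2 == x1) x2 <- min(b, x2 + 1)
    }
  }
  for (k in a:b) score(k)
  invisible(NULL)
}

#' Fit a geographically weighted regression of immune on epithelial intensity
#'
#' At every masked grid point a weighted least-squares line is fitted with
#' distance-decayed weights over the other masked points, yielding spatially
#' varying intercept and slope fields. The adaptive bandwidth (neighbour
#' count) is selected by [select_bandwidth_aicc()]. Rank-deficient local
#' fits (e.g. locally constant predictor) are dropped from the coefficient
#' sample and counted in the diagnostics.
#'
#' @param epi,imm `intensity_grid`s for the epithelial (predictor) and
#'   immune (response) phenotypes on the same grid.
#' @param mask Logical matrix from [threshold_mask()].
#' @param type Spatial kernel, `"bisquare"` or `"gaussian"`.
#' @param k_min Minimum adaptive neighbour count (default 10).
#' @param n_min Minimum masked grid points required (default 30).
#' @param k Optional fixed neighbour count; skips bandwidth selection.
#' @return An object of class `gwr_fit`; see [tidy.gwr_fit()] for the
#'   per-location coefficient table and [glance.gwr_fit()] for diagnostics.
#' @export
fit_gwr <- function(epi, imm, mask, type = c("bisquare", "gaussian"),
                    k_min = 10, n_min = 30, k = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(epi, "intensity_grid"), inherits(imm, "intensity_grid"))
  if (!identical(dim(epi$values), dim(mask)) ||
      !identical(dim(imm$values), dim(mask))) {
    stop("epi, imm and mask must share one grid", call. = FALSE)
  }
  n <- sum(mask)
  if (n < n_min) {
    stop(
      "only ", n, " masked grid points (minimum ", n_min, ") for image ",
      epi$label,
      call. = FALSE
    )
  }
  uu <- expand.grid(x = epi$grid$x, y = epi$grid$y)
  sel <- as.vector(mask)
  coords <- cbind(uu$x[sel], uu$y[sel])
  x <- as.vector(epi$values)[sel]
  y <- as.vector(imm$values)[sel]
  nb <- neighbour_structure(coords)
  if (is.null(k)) {
    bw <- select_bandwidth_aicc(x, y, coords, type = type, k_min = k_min,
                                nb = nb)
    k <- bw$k
  }
  pass <- gwr_pass(x, y, nb$ord, nb$dsort, k, type)
  tr_s <- sum(pass$hat[pass$ok])
  structure(
    list(
      coords = tibble::tibble(
        x = coords[, 1], y = coords[, 2],
        epi = !!x, imm = !!y,
        beta0 = pass$beta0, beta1 = pass$beta1,
        fitted = pass$fitted, residual = !!y - pass$fitted,
        hat = pass$hat, ok = pass$ok
      ),
      bandwidth_k = k, kernel = type,
      hat_trace = tr_s,
      aicc = as.numeric(gwr_aicc(y[pass$ok], pass$fitted[pass$ok], tr_s)),
      n_masked = n, n_dropped = sum(!pass$ok),
      label = epi$label
    ),
    class = "gwr_fit"
  )
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf(
    "<gwr_fit %s: %d masked points (%d dropped), k = %d (%s), AICc = %.2f>\n",
    x$label, x$n_masked, x$n_dropped, x$bandwidth_k, x$kernel, x$aicc
  ))
  invisible(x)
}

#' Tidy a GWR fit into its per-location coefficient table
#'
#' @param x A `gwr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per retained masked grid point: location,
#'   predictor/response intensities, `beta0`, `beta1`, `fitted`, `residual`,
#'   `hat`.
#' @method tidy gwr_fit
#' @export
tidy.gwr_fit <- function(x, ...) {
  dplyr::select(
    dplyr::filter(x$coords, .data$ok),
    -"ok"
  )
}

#' One-row summary of a GWR fit
#'
#' @param x A `gwr_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_masked`, `n_dropped`, `bandwidth_k`, `kernel`,
#'   `hat_trace`, `aicc`, `rss`.
#' @method glance gwr_fit
#' @export
glance.gwr_fit <- function(x, ...) {
  tibble::tibble(
    n_masked = x$n_masked, n_dropped = x$n_dropped,
    bandwidth_k = x$bandwidth_k, kernel = x$kernel,
    hat_trace = x$hat_trace, aicc = x$aicc,
    rss = sum(x$coords$residual[x$coords$ok]^2)
  )
}
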