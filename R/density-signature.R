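#' Fit the cohort-wide coefficient scaling
#'
#' GWR coefficients are mapped onto \[0, 1\] by a single affine
#' transformation using their global minimum and maximum across the whole
#' cohort, so all signatures live on one common support. The fitted spec is
#' stored and reused (with clipping) for held-out data.
#'
#' @param values Numeric vector of all coefficient values in the cohort.
#' @return An object of class `scaling_spec` with `global_min`,
#'   `global_max`.
#' @export
fit_scaling <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need at least two finite coefficient values", call. = FALSE)
  }
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) {
    stop("degenerate cohort: all coefficient values identical", call. = FALSE)
  }
  structure(list(global_min = lo, global_max = hi), class = "scaling_spec")
}

#' Apply a fitted scaling, clipping out-of-range values
#'
#' @param values Raw coefficient values.
#' @param scaling A [fit_scaling()] spec.
#' @return Values scaled to \[0, 1\]; out-of-range inputs are clipped to the
#'   boundary and counted in the `n_clipped` attribute.
#' @export
apply_scaling <- function(values, scaling) {
  stopifnot(inherits(scaling, "scaling_spec"))
  z <- (values - scaling$global_min) /
    (scaling$global_max - scaling$global_min)
  n_clipped <- sum(z < 0 | z > 1)
  z <- pmin(1, pmax(0, z))
  attr(z, "n_clipped") <- n_clipped
  z
}

#' Density signature of a coefficient sample
#'
#' Gaussian kernel density estimate of the scaled coefficients on a uniform
#' grid over \[0, 1\], boundary-corrected by reflection at both edges,
#' floored at 1e-10 and renormalised to integrate (trapezoid rule) to
#' exactly 1. The bandwidth defaults to Silverman's rule on the scaled
#' sample.
#'
#' @param values Raw coefficient values of one image or subject.
#' @param scaling A [fit_scaling()] spec.
#' @param m Evaluation grid size (default 512).
#' @param bw Kernel bandwidth on the scaled axis; `NULL` (default) for
#'   Silverman's rule (`stats::bw.nrd0`), floored at 1e-3.
#' @return A list of class `density_signature` with `t` (grid), `f`
#'   (density values) and metadata.
#' @export
coefficient_density <- function(values, scaling, m = 512, bw = NULL) {
  z <- apply_scaling(values[is.finite(values)], scaling)
  if (length(z) < 2) {
    stop("need at least two coefficient values for a density", call. = FALSE)
  }
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(as.numeric(z)), error = function(e) 0)
  }
  bw <- max(bw, 1e-3)
  t_grid <- seq(0, 1, length.out = m)
  f <- reflected_kde(as.numeric(z), t_grid, bw)
  f <- pmax(f, 1e-10)
  f <- f / trapz(t_grid, f)
  structure(
    list(t = t_grid, f = f, n = length(z), bw = bw,
         n_clipped = attr(z, "n_clipped")),
    class = "density_signature"
  )
}

# Gaussian KDE on [0, 1] with reflection at both boundaries.
reflected_kde <- function(z, t_grid, bw) {
  f <- function(centers) {
    rowMeans(stats::dnorm(outer(t_grid, centers, "-"), sd = bw))
  }
  f(z) + f(-z) + f(2 - z)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# trapezoid quadrature weights on a uniform grid
trapz_weights <- function(t_grid) {
  m <- length(t_grid)
  dt <- t_grid[2] - t_grid[1]
  w <- rep(dt, m)
  w[c(1, m)] <- dt / 2
  w
}

#' Extract per-owner coefficient samples from a cohort of GWR fits
#'
#' Collects the chosen coefficient (slope by default — the epithelial
#' effect on immune intensity) from every image's GWR fit into one
#' list-column tibble, optionally pooling all of a subject's images into a
#' single subject-level sample (concatenation of values).
#'
#' @param fits Named list of `gwr_fit` objects; names `subject/image`.
#' @param meta Tibble with columns `subject_id`, `image_id`, `group` (one
#'   row per fit, same order as `fits`).
#' @param coefficient `"beta1"` (default), `"beta0"`, or `"both"` (stacked).
#' @param level `"image"` (one sample per image) or `"subject"` (pool all
#'   images of a subject).
#' @return Tibble with columns `owner`, `group`, and list-column `values`.
#' @export
coefficient_samples <- function(fits, meta,
                                coefficient = c("beta1", "beta0", "both"),
                                level = c("image", "subject")) {
  coefficient <- match.arg(coefficient)
  level <- match.arg(level)
  pull_values <- function(fit) {
    tab <- tidy.gwr_fit(fit)
    switch(coefficient,
      beta1 = tab$beta1,
      beta0 = tab$beta0,
      both = c(tab$beta0, tab$beta1)
    )
  }
  per_image <- meta
  per_image$values <- lapply(fits, pull_values)
  if (level == "image") {
    return(tibble::tibble(
      owner = per_image$image_id, group = per_image$group,
      values = per_image$values
    ))
  }
  pooled <- per_image |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(
      values = list(unlist(.data$values, use.names = FALSE)),
      .groups = "drop"
    )
  tibble::tibble(
    owner = pooled$subject_id, group = pooled$group, values = pooled$values
  )
}

#' Build the signature set of a cohort
#'
#' Fits the global min-max scaling on all coefficient values, then computes
#' one density signature per owner (image or subject).
#'
#' @param samples Tibble from [coefficient_samples()] (`owner`, `group`,
#'   list-column `values`).
#' @param level Analysis level label carried on the result.
#' @param m Density grid size (default 512).
#' @param bw Fixed KDE bandwidth, or `NULL` for Silverman per sample.
#' @param scaling Optional pre-fitted [fit_scaling()] spec (for held-out
#'   data); default fits on `samples`.
#' @return An object of class `signature_set`: density matrix `f` (owners
#'   by grid), grid `t`, `meta` tibble (`owner`, `group`), the `scaling`,
#'   and `level`.
#' @export
signature_set <- function(samples, level = "image", m = 512, bw = NULL,
                          scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- fit_scaling(unlist(samples$values))
  }
  sigs <- lapply(samples$values, coefficient_density,
                 scaling = scaling, m = m, bw = bw)
  f <- do.call(rbind, lapply(sigs, `[[`, "f"))
  rownames(f) <- samples$owner
  structure(
    list(
      f = f, t = sigs[[1]]$t,
      meta = tibble::tibble(owner = samples$owner, group = samples$group),
      scaling = scaling, level = level, bw = bw
    ),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "<signature_set: %d %s-level signatures on %d-point grid, %d group(s)>\n",
    nrow(x$f), x$level, length(x$t), length(unique(x$meta$group))
  ))
  invisible(x)
}

#' @method as_tibble signature_set
#' @export
as_tibble.signature_set <- function(x, ...) {
  tibble::tibble(
    owner = rep(x$meta$owner, each = length(x$t)),
    group = rep(x$meta$group, each = length(x$t)),
    t = rep(x$t, times = nrow(x$f)),
    f = as.vector(t(x$f))
  )
}

#' Plot the density signatures of a cohort
#'
#' One curve per owner, coloured and facetted by group — the standard view
#' of the per-image (or per-subject) interaction signatures.
#'
#' @param object A `signature_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_set
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- as_tibble.signature_set(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$t, y = .data$f, group = .data$owner,
                 colour = .data$group)
  ) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = "scaled GWR coefficient", y = "density",
      title = sprintf("%s-level interaction signatures", object$level)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
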