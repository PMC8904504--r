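#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end flow with its default. All
#' lengths are in the coordinate units of the input tables.
#'
#' @param sigma Intensity kernel sd; `NULL` (default) for
#'   [default_sigma()] of each image's window.
#' @param grid_n Grid cells along the longer window side (default 128).
#' @param tau Absolute epithelial intensity threshold, or `NULL` (default)
#'   for the cohort 1st-percentile rule ([cohort_tau()]).
#' @param tau_prob Quantile level of the cohort tau rule (default 0.01).
#' @param gwr_kernel `"bisquare"` (default) or `"gaussian"`.
#' @param k_min Minimum adaptive neighbour count (default 10).
#' @param n_min Minimum masked grid points per image (default 30).
#' @param coefficient Signature coefficient: `"beta1"` (default, the
#'   epithelial effect on immune intensity), `"beta0"`, or `"both"`.
#' @param m Density grid size (default 512).
#' @param kde_bw Fixed KDE bandwidth or `NULL` for Silverman's rule.
#' @param variance_threshold Tangent-PCA retained variance (default
#'   0.9999).
#' @param level `"image"` or `"subject"`.
#' @param significance_threshold AUC flagging threshold (default 0.75).
#' @param min_per_type Inclusion criterion (default 5).
#' @param window Fixed [obs_window()] for all images, or `NULL` for
#'   per-image bounding boxes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sigma = NULL, grid_n = 128, tau = NULL,
                            tau_prob = 0.01,
                            gwr_kernel = c("bisquare", "gaussian"),
                            k_min = 10, n_min = 30,
                            coefficient = c("beta1", "beta0", "both"),
                            m = 512, kde_bw = NULL,
                            variance_threshold = 0.9999,
                            level = c("image", "subject"),
                            significance_threshold = 0.75,
                            min_per_type = 5, window = NULL) {
  structure(
    list(
      sigma = sigma, grid_n = grid_n, tau = tau, tau_prob = tau_prob,
      gwr_kernel = match.arg(gwr_kernel), k_min = k_min, n_min = n_min,
      coefficient = match.arg(coefficient), m = m, kde_bw = kde_bw,
      variance_threshold = variance_threshold, level = match.arg(level),
      significance_threshold = significance_threshold,
      min_per_type = min_per_type, window = window
    ),
    class = "pipeline_config"
  )
}

#' Per-image GWR coefficient fields for a whole cohort
#'
#' Applies the inclusion criteria, estimates both phenotype intensity
#' surfaces per image, fixes the cohort-wide intensity threshold, and fits
#' the GWR at every image. This is the shared front half of the pipeline.
#'
#' @param cells Cohort cell tibble.
#' @param config A [pipeline_config()].
#' @return List with `fits` (named list of `gwr_fit`), `meta` (per-image
#'   tibble), `tau`, `excluded`, and `diagnostics` (per-image glance rows).
#' @export
cohort_gwr <- function(cells, config = pipeline_config()) {
  incl <- apply_inclusion_criteria(cells, config$min_per_type)
  if (nrow(incl$retained) == 0) {
    stop("no image passes the inclusion criteria", call. = FALSE)
  }
  per_image <- split_images(incl$retained)
  prepared <- lapply(per_image, function(img) {
    win <- if (is.null(config$window)) {
      infer_window(img, "bbox")
    } else {
      infer_window(img, "fixed", window = config$window)
    }
    sigma <- if (is.null(config$sigma)) default_sigma(win) else config$sigma
    grid <- make_grid(win, config$grid_n)
    list(
      img = img,
      epi = kernel_intensity(
        dplyr::filter(img, .data$phenotype == "epithelial"),
        win, grid, sigma, label = img$image_id[1]
      ),
      imm = kernel_intensity(
        dplyr::filter(img, .data$phenotype == "immune"),
        win, grid, sigma, label = img$image_id[1]
      )
    )
  })
  tau <- if (is.null(config$tau)) {
    cohort_tau(lapply(prepared, `[[`, "epi"), config$tau_prob)
  } else {
    config$tau
  }
  fits <- lapply(prepared, function(p) {
    mask <- suppressWarnings(threshold_mask(p$epi, tau, config$n_min))
    fit_gwr(p$epi, p$imm, mask, type = config$gwr_kernel,
            k_min = config$k_min, n_min = config$n_min)
  })
  meta <- dplyr::bind_rows(lapply(prepared, function(p) {
    tibble::tibble(
      subject_id = p$img$subject_id[1],
      image_id = p$img$image_id[1],
      group = p$img$group[1]
    )
  }))
  diagnostics <- dplyr::bind_cols(
    meta,
    dplyr::bind_rows(lapply(fits, glance.gwr_fit))
  )
  list(fits = fits, meta = meta, tau = tau, excluded = incl$excluded,
       diagnostics = diagnostics)
}

#' Cohort density signatures at a chosen analysis level
#'
#' Front half ([cohort_gwr()]) plus coefficient extraction, global min-max
#' scaling and per-owner KDE signatures.
#'
#' @param cells Cohort cell tibble.
#' @param config A [pipeline_config()]; its `level` selects image- or
#'   subject-level signatures.
#' @param gwr Optional precomputed [cohort_gwr()] result, to reuse across
#'   levels.
#' @return A [signature_set()] with the GWR result attached as attribute
#'   `gwr`.
#' @export
cohort_signatures <- function(cells, config = pipeline_config(), gwr = NULL) {
  if (is.null(gwr)) gwr <- cohort_gwr(cells, config)
  samples <- coefficient_samples(gwr$fits, gwr$meta,
                                 coefficient = config$coefficient,
                                 level = config$level)
  sigs <- signature_set(samples, level = config$level, m = config$m,
                        bw = config$kde_bw)
  attr(sigs, "gwr") <- gwr
  sigs
}

#' Run the full framework end to end
#'
#' Executes the four framework stages in order — intensity surfaces, GWR
#' coefficient fields, density signatures, tangent-PCA probit
#' classification — and returns every stage's artifact plus the pairwise
#' results table.
#'
#' @param cells Cohort cell tibble (read or simulated).
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `results` (pairwise table),
#'   `signatures`, `gwr` diagnostics, `tau`, `excluded`, `config`.
#' @export
run_pipeline <- function(cells, config = pipeline_config()) {
  gwr <- cohort_gwr(cells, config)
  sigs <- cohort_signatures(cells, config, gwr = gwr)
  results <- run_all_pairs(
    sigs,
    significance_threshold = config$significance_threshold,
    variance_threshold = config$variance_threshold
  )
  structure(
    list(
      results = results, signatures = sigs,
      diagnostics = gwr$diagnostics, tau = gwr$tau,
      excluded = gwr$excluded, config = config
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result: %d pairwise comparison(s) at %s level, tau = %.3g>\n",
    nrow(x$results), x$config$level, x$tau
  ))
  print(x$results)
  invisible(x)
}

#' Plot a GWR slope field
#'
#' @param object A `gwr_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the local slope over the masked grid.
#' @method autoplot gwr_fit
#' @export
autoplot.gwr_fit <- function(object, ...) {
  df <- tidy.gwr_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$beta1)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x", y = "y", fill = "local slope",
      title = sprintf("GWR slope field (%s, k = %d)",
                      object$label, object$bandwidth_k)
    ) +
    ggplot2::theme_minimal()
}
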