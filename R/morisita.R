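#' Quadrat counts of the two phenotypes over a window
#'
#' Partitions the window into a `q_x` by `q_y` grid of equal quadrats and
#' counts epithelial and immune cells per quadrat. Binning is half-open
#' `[x_j, x_{j+1})` with the last bin closed, so a point on an interior
#' boundary belongs to the right/upper quadrat.
#'
#' @param cells Cell tibble of one image.
#' @param window An [obs_window()] containing every cell.
#' @param q_x,q_y Quadrat grid dimensions (default 10 x 10).
#' @return List of class `quadrat_counts`: integer vectors `e` and `i` of
#'   length `q_x * q_y` plus totals `E`, `I`.
#' @export
quadrat_counts <- function(cells, window, q_x = 10, q_y = 10) {
  stopifnot(q_x >= 1, q_y >= 1)
  inside <- cells$x >= window$x_min & cells$x <= window$x_max &
    cells$y >= window$y_min & cells$y <= window$y_max
  if (!all(inside)) {
    stop("cell(s) outside the quadrat window", call. = FALSE)
  }
  bin <- function(v, lo, hi, q) {
    idx <- 1 + floor(q * (v - lo) / (hi - lo))
    pmin(idx, q) # points exactly on the upper window edge go in the last bin
  }
  ix <- bin(cells$x, window$x_min, window$x_max, q_x)
  iy <- bin(cells$y, window$y_min, window$y_max, q_y)
  quad <- (iy - 1) * q_x + ix
  count_type <- function(type) {
    tabulate(quad[cells$phenotype == type], nbins = q_x * q_y)
  }
  e <- count_type("epithelial")
  i <- count_type("immune")
  structure(
    list(e = e, i = i, E = sum(e), I = sum(i), q_x = q_x, q_y = q_y),
    class = "quadrat_counts"
  )
}

#' Morisita-Horn co-localization index
#'
#' `MH = 2 sum_q e_q i_q / ((sum_q e_q^2 / E^2 + sum_q i_q^2 / I^2) E I)`,
#' in \[0, 1\]: 1 when the two count profiles are proportional across
#' quadrats, 0 when their occupancies are disjoint. Symmetric in the two
#' types and invariant to scaling either profile.
#'
#' @param counts A [quadrat_counts()] object, or a numeric vector `e` (then
#'   supply `i`).
#' @param i Immune counts when `counts` is a bare epithelial count vector.
#' @return The index, a scalar in \[0, 1\].
#' @export
morisita_horn <- function(counts, i = NULL) {
  if (inherits(counts, "quadrat_counts")) {
    e <- counts$e
    i <- counts$i
  } else {
    e <- counts
  }
  E <- sum(e)
  I <- sum(i)
  if (E == 0 || I == 0) {
    stop("Morisita-Horn index undefined: a phenotype has zero cells",
         call. = FALSE)
  }
  2 * sum(e * i) / ((sum(e^2) / E^2 + sum(i^2) / I^2) * E * I)
}

#' Per-image Morisita-Horn indices of a cohort
#'
#' Images failing the inclusion criteria are excluded here too, so the
#' baseline analysis runs on the same cohort as the signature analysis.
#'
#' @param cells Cohort cell tibble.
#' @param q_x,q_y Quadrat grid dimensions (default 10 x 10).
#' @param window Fixed window for all images, or `NULL` to use each image's
#'   bounding box.
#' @param min_per_type Inclusion threshold (default 5).
#' @return Tibble: `subject_id`, `image_id`, `group`, `mh`.
#' @export
morisita_horn_cohort <- function(cells, q_x = 10, q_y = 10, window = NULL,
                                 min_per_type = 5) {
  kept <- apply_inclusion_criteria(cells, min_per_type)$retained
  per_image <- split_images(kept)
  rows <- lapply(per_image, function(img) {
    win <- if (is.null(window)) infer_window(img, "bbox") else window
    tibble::tibble(
      subject_id = img$subject_id[1],
      image_id = img$image_id[1],
      group = img$group[1],
      mh = morisita_horn(quadrat_counts(img, win, q_x, q_y))
    )
  })
  dplyr::bind_rows(rows)
}
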