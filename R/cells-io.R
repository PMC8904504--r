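#' Observation window
#'
#' An axis-aligned rectangle containing a cell point pattern. All coordinates
#' are in the units of the input file (pixels or microns); no unit conversion
#' is ever performed, and downstream bandwidths are expressed in the same
#' units.
#'
#' @param x_min,x_max,y_min,y_max Window edges; `x_max > x_min`,
#'   `y_max > y_min`.
#' @return An object of class `obs_window`.
#' @export
#' @examples
#' obs_window(0, 600, 0, 600)
obs_window <- function(x_min, x_max, y_min, y_max) {
  vals <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (any(!is.finite(vals))) {
    stop("window edges must be finite", call. = FALSE)
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("invalid window: need x_max > x_min and y_max > y_min", call. = FALSE)
  }
  structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
    class = "obs_window"
  )
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf(
    "<obs_window [%g, %g] x [%g, %g]>\n",
    x$x_min, x$x_max, x$y_min, x$y_max
  ))
  invisible(x)
}

window_area <- function(window) {
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

window_diag <- function(window) {
  sqrt((window$x_max - window$x_min)^2 + (window$y_max - window$y_min)^2)
}

#' Default intensity-kernel bandwidth for a window
#'
#' Scale-relative default used throughout the package: one thirty-second of
#' the window diagonal. Keeps synthetic tests dimensionless and adapts to
#' whatever length unit the coordinates carry.
#'
#' @param window An [obs_window()].
#' @return A positive scalar bandwidth (standard deviation of the isotropic
#'   Gaussian smoothing kernel), in coordinate units.
#' @export
default_sigma <- function(window) {
  window_diag(window) / 32
}

.phenotypes <- c("epithelial", "immune", "other")

#' Read a cell coordinate table
#'
#' Reads a delimited text export of per-cell coordinates and phenotype calls
#' (one row per cell) into the package's canonical tibble layout. The column
#' map names which input columns hold the subject, image, group, x, y and
#' phenotype fields, and optionally recodes marker-logic phenotype strings
#' (e.g. `"CD3+CD8+"`) onto the closed vocabulary
#' `{epithelial, immune, other}`. Phenotypes absent from the recoding and not
#' already in the vocabulary are mapped to `"other"`.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param column_map Named list with elements `subject_id`, `image_id`,
#'   `group`, `x`, `y`, `phenotype` giving input column names, and an optional
#'   `recode` named character vector mapping input phenotype strings to
#'   vocabulary labels.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A tibble with columns `subject_id`, `image_id`, `group`, `x`, `y`,
#'   `phenotype` (one row per cell; possibly zero rows).
#' @export
read_cell_table <- function(path, column_map = NULL, delim = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  canonical <- c("subject_id", "image_id", "group", "x", "y", "phenotype")
  if (is.null(column_map)) {
    column_map <- as.list(stats::setNames(canonical, canonical))
  }
  missing_keys <- setdiff(canonical, names(column_map))
  if (length(missing_keys) > 0) {
    stop(
      "column_map is missing entries for: ",
      paste(missing_keys, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  src_cols <- vapply(column_map[canonical], identity, character(1))
  absent <- setdiff(unname(src_cols), names(raw))
  if (length(absent) > 0) {
    stop(
      "mapped column(s) not present in ", path, ": ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    subject_id = as.character(raw[[src_cols[["subject_id"]]]]),
    image_id = as.character(raw[[src_cols[["image_id"]]]]),
    group = as.character(raw[[src_cols[["group"]]]]),
    x = suppressWarnings(as.numeric(raw[[src_cols[["x"]]]])),
    y = suppressWarnings(as.numeric(raw[[src_cols[["y"]]]])),
    phenotype = as.character(raw[[src_cols[["phenotype"]]]])
  )
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad) > 0) {
    stop(
      "non-numeric or non-finite coordinate at data row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  recode <- column_map$recode
  if (!is.null(recode)) {
    hit <- out$phenotype %in% names(recode)
    out$phenotype[hit] <- unname(recode[out$phenotype[hit]])
  }
  out$phenotype[!(out$phenotype %in% .phenotypes)] <- "other"
  out
}

#' Write a cell table in the canonical dialect
#'
#' Comma-separated, UTF-8, columns
#' `subject_id,image_id,group,x,y,phenotype`. Inverse of [read_cell_table()]
#' with the default column map.
#'
#' @param cells A cell tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(
    cells[, c("subject_id", "image_id", "group", "x", "y", "phenotype")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Per-image phenotype counts
#'
#' @param cells A cell tibble (any number of images).
#' @return A tibble with one row per (subject_id, image_id, group) and
#'   columns `n_epithelial`, `n_immune`, `n_other`, `n_total`.
#' @export
image_summary <- function(cells) {
  cells |>
    dplyr::group_by(.data$subject_id, .data$image_id, .data$group) |>
    dplyr::summarise(
      n_epithelial = sum(.data$phenotype == "epithelial"),
      n_immune = sum(.data$phenotype == "immune"),
      n_other = sum(.data$phenotype == "other"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}

#' Apply the minimum-representation inclusion criteria
#'
#' An image is retained only if it contains at least `min_per_type`
#' epithelial and at least `min_per_type` immune cells; images failing the
#' rule are excluded with a logged reason. The operation is idempotent and
#' partitions the input images into retained and excluded sets.
#'
#' @param cells A cell tibble covering one or more images.
#' @param min_per_type Minimum cells of each of the two phenotypes
#'   (default 5).
#' @return A list with elements `retained` (cell tibble restricted to
#'   retained images) and `excluded` (tibble of `subject_id`, `image_id`,
#'   counts and a `reason` string; zero rows if nothing was excluded).
#' @export
apply_inclusion_criteria <- function(cells, min_per_type = 5) {
  if (nrow(cells) == 0) {
    return(list(retained = cells, excluded = tibble::tibble(
      subject_id = character(), image_id = character(),
      n_epithelial = integer(), n_immune = integer(), reason = character()
    )))
  }
  summ <- image_summary(cells)
  summ$keep <- summ$n_epithelial >= min_per_type & summ$n_immune >= min_per_type
  excluded <- summ |>
    dplyr::filter(!.data$keep) |>
    dplyr::mutate(reason = sprintf(
      "requires >= %d epithelial and >= %d immune cells (found %d, %d)",
      min_per_type, min_per_type, .data$n_epithelial, .data$n_immune
    )) |>
    dplyr::select(
      "subject_id", "image_id", "n_epithelial", "n_immune", "reason"
    )
  kept_ids <- summ$image_id[summ$keep]
  retained <- dplyr::filter(cells, .data$image_id %in% kept_ids)
  list(retained = retained, excluded = excluded)
}

#' Infer or validate the observation window of one image
#'
#' @param cells Cell tibble of a single image (`bbox` mode needs at least
#'   one cell).
#' @param mode `"bbox"`: bounding box of the cells expanded by `margin` on
#'   every side. `"fixed"`: return `window` after validating that every cell
#'   lies inside it.
#' @param margin Margin added on each side in `bbox` mode (default 0).
#' @param window The fixed window (`fixed` mode).
#' @return An [obs_window()].
#' @export
infer_window <- function(cells, mode = c("bbox", "fixed"), margin = 0,
                         window = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(window)) stop("fixed mode requires a window", call. = FALSE)
    stopifnot(inherits(window, "obs_window"))
    if (nrow(cells) > 0) {
      inside <- cells$x >= window$x_min & cells$x <= window$x_max &
        cells$y >= window$y_min & cells$y <= window$y_max
      if (!all(inside)) {
        stop(
          sum(!inside), " cell(s) fall outside the fixed window",
          call. = FALSE
        )
      }
    }
    return(window)
  }
  if (nrow(cells) == 0) {
    stop("bbox mode requires at least one cell", call. = FALSE)
  }
  obs_window(
    min(cells$x) - margin, max(cells$x) + margin,
    min(cells$y) - margin, max(cells$y) + margin
  )
}

#' Split a cohort tibble into per-image tibbles
#'
#' @param cells Cohort cell tibble.
#' @return A named list of per-image tibbles, names `subject_id/image_id`.
#' @export
split_images <- function(cells) {
  key <- paste(cells$subject_id, cells$image_id, sep = "/")
  split(cells, factor(key, levels = unique(key)))
}
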