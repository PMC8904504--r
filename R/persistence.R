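#' Persist and reload a signature set
#'
#' Writes the density matrix as CSV (rows = owners, columns = grid points)
#' plus a JSON sidecar with the scaling, level, grid and KDE settings —
#' enough to re-project held-out data in a later session.
#'
#' @param sigs A [signature_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_signatures <- function(sigs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- tibble::as_tibble(as.data.frame(sigs$f))
  names(df) <- paste0("f", seq_along(sigs$t))
  readr::write_csv(
    dplyr::bind_cols(sigs$meta, df),
    file.path(dir, "signatures.csv"), progress = FALSE
  )
  jsonlite::write_json(
    list(
      level = sigs$level, m = length(sigs$t),
      t_min = sigs$t[1], t_max = sigs$t[length(sigs$t)],
      kde_bw = sigs$bw,
      scaling = list(global_min = sigs$scaling$global_min,
                     global_max = sigs$scaling$global_max)
    ),
    file.path(dir, "signatures.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(dir) {
  meta_json <- jsonlite::read_json(file.path(dir, "signatures.json"))
  df <- readr::read_csv(file.path(dir, "signatures.csv"),
                        show_col_types = FALSE, progress = FALSE)
  f <- as.matrix(df[, paste0("f", seq_len(meta_json$m))])
  rownames(f) <- df$owner
  dimnames(f)[[2]] <- NULL
  structure(
    list(
      f = f,
      t = seq(meta_json$t_min, meta_json$t_max, length.out = meta_json$m),
      meta = tibble::tibble(owner = df$owner, group = df$group),
      scaling = structure(
        list(global_min = meta_json$scaling$global_min,
             global_max = meta_json$scaling$global_max),
        class = "scaling_spec"
      ),
      level = meta_json$level,
      bw = meta_json$kde_bw
    ),
    class = "signature_set"
  )
}

#' Persist and reload a tangent-PCA model
#'
#' CSV holds the Karcher mean and the retained tangent basis by grid
#' point; JSON holds eigenvalues, threshold and grid. The reloaded model
#' supports [project_scores()] in a later process.
#'
#' @param model A [tangent_pca()] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tangent_pca <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  basis <- as.data.frame(model$vectors)
  if (model$k > 0) names(basis) <- paste0("e", seq_len(model$k))
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(t = model$t, mean = model$mean), basis),
    file.path(dir, "tangent_pca.csv"), progress = FALSE
  )
  jsonlite::write_json(
    list(k = model$k, values = model$values,
         variance_threshold = model$variance_threshold,
         var_explained = model$var_explained,
         degenerate = model$degenerate),
    file.path(dir, "tangent_pca.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_tangent_pca
#' @export
read_tangent_pca <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "tangent_pca.json"),
                              simplifyVector = TRUE)
  df <- readr::read_csv(file.path(dir, "tangent_pca.csv"),
                        show_col_types = FALSE, progress = FALSE)
  k <- as.integer(meta$k)
  vectors <- if (k > 0) {
    as.matrix(df[, paste0("e", seq_len(k))])
  } else {
    matrix(0, nrow(df), 0)
  }
  dimnames(vectors) <- NULL
  structure(
    list(mean = df$mean, vectors = vectors, values = meta$values,
         k = k, scores = NULL, t = df$t,
         variance_threshold = meta$variance_threshold,
         var_explained = meta$var_explained,
         degenerate = isTRUE(meta$degenerate)),
    class = "tangent_pca"
  )
}
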