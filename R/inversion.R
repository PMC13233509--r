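#' Per-pixel rasters for named features
#'
#' Recomputes model features per pixel from a scene bundle: RGB digital
#' numbers and colour indices, band reflectances and vegetation indices,
#' moving-window texture features, and texture indices. Plot-aggregate-only
#' features (currently `FVC`, which is defined as an ROI mean) cannot be
#' rasterized and raise an error naming them.
#'
#' @param bundle A `scene_bundle`.
#' @param features Character vector of feature names.
#' @param spec A [glcm_spec()].
#' @param red_edge Red-edge band for the red-edge indices.
#' @return Named list of numeric matrices (NA where undefined, e.g. texture
#'   borders).
#' @export
feature_rasters <- function(bundle, features, spec = glcm_spec(),
                            red_edge = "720") {
  stopifnot(inherits(bundle, "scene_bundle"))
  plot_only <- intersect(features, "FVC")
  if (length(plot_only) > 0) {
    stop("plot-aggregate-only feature(s) cannot be rasterized: ",
         paste(plot_only, collapse = ", "))
  }
  d <- dim(bundle$reflectance)[1:2]
  n_px <- prod(d)
  band_lab <- paste0("R", bundle$band_nm)

  # pixel table of the primitive inputs
  px <- tibble(R = as.numeric(bundle$rgb_dn[, , 1]),
               G = as.numeric(bundle$rgb_dn[, , 2]),
               B = as.numeric(bundle$rgb_dn[, , 3]))
  for (b in seq_along(band_lab)) {
    px[[band_lab[b]]] <- as.numeric(bundle$reflectance[, , b])
  }

  ci_names <- ci_feature_names()
  vi_names <- vi_feature_names()
  needs_ci <- any(features %in% setdiff(ci_names, c("R", "G", "B")))
  needs_vi <- any(features %in% vi_names)
  if (needs_ci) px <- color_indices(px)
  if (needs_vi) px <- vegetation_indices(px, red_edge = red_edge)

  # texture features referenced directly or inside texture indices
  tf_direct <- grep(tf_col_pattern(), features, value = TRUE)
  ti_feats <- grep(ti_col_pattern(), features, value = TRUE)
  tf_from_ti <- unlist(purrr::map(ti_feats, function(f) {
    inner <- sub("^(NDTI|RTI|DTI)\\((.*)\\)$", "\\2", f)
    strsplit(inner, ",")[[1]]
  }))
  tf_all <- unique(c(tf_direct, trimws(tf_from_ti)))
  if (length(tf_all) > 0) {
    bands_needed <- unique(sub("-(.*)$", "", tf_all))
    maps <- purrr::map(setNames(bands_needed, bands_needed), function(bn) {
      bi <- match(as.integer(bn), bundle$band_nm)
      if (is.na(bi)) stop("unknown texture band ", bn)
      texture_maps(bundle$reflectance[, , bi], spec)
    })
    for (f in tf_all) {
      parts <- strsplit(f, "-")[[1]]
      px[[f]] <- as.numeric(maps[[parts[1]]][[parts[2]]])
    }
    for (f in ti_feats) {
      fam <- sub("\\(.*$", "", f)
      inner <- trimws(strsplit(sub("^(NDTI|RTI|DTI)\\((.*)\\)$", "\\2", f),
                               ",")[[1]])
      t1 <- px[[inner[1]]]; t2 <- px[[inner[2]]]
      v <- switch(fam,
                  NDTI = (t1 - t2) / (t1 + t2),
                  RTI = t1 / t2,
                  DTI = t1 - t2)
      v[!is.finite(v)] <- NA_real_
      px[[f]] <- v
    }
  }
  unknown <- setdiff(features, names(px))
  if (length(unknown) > 0) {
    stop("cannot compute per-pixel rasters for: ",
         paste(unknown, collapse = ", "))
  }
  purrr::map(setNames(features, features),
             ~ matrix(px[[.x]], d[1], d[2]))
}

#' Per-pixel PPC inversion map
#'
#' Applies a fitted model to per-pixel feature rasters of a scene, giving a
#' PPC surface. Features are recomputed per pixel ([feature_rasters()]),
#' standardized with the model's training scaler, and fed to the model;
#' pixels with any missing feature (e.g. texture borders) propagate as
#' missing.
#'
#' @param model A `ppc_model`.
#' @param bundle A `scene_bundle`.
#' @param spec A [glcm_spec()].
#' @param red_edge Red-edge band for the red-edge indices.
#' @return Numeric matrix of predicted PPC (g/kg).
#' @export
inversion_map <- function(model, bundle, spec = glcm_spec(),
                          red_edge = "720") {
  stopifnot(inherits(model, "ppc_model"))
  rasters <- feature_rasters(bundle, model$features, spec, red_edge)
  d <- dim(rasters[[1]])
  X <- do.call(cbind, purrr::map(rasters, as.numeric))
  colnames(X) <- model$features
  pred <- predict(model, as_tibble(X))
  matrix(pred, d[1], d[2])
}

#' Plot a PPC inversion map
#'
#' @param map Matrix from [inversion_map()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_inversion_map <- function(map, title = "Predicted PPC (g/kg)") {
  df <- tidyr::expand_grid(row = seq_len(nrow(map)),
                           col = seq_len(ncol(map))) |>
    mutate(ppc = map[cbind(.data$row, .data$col)])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$ppc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "PPC", title = title) +
    ggplot2::theme_minimal()
}
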