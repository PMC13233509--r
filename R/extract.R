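#' Extract the per-plot feature table from a scene
#'
#' Aggregates a scene bundle to one row per plot and appends the requested
#' feature families: colour indices (`ci`, from mean RGB digital numbers —
#' aggregate-then-index), vegetation indices (`vi`, from mean band
#' reflectances), dimidiate-pixel fractional vegetation cover (`fvc`,
#' scene-wide NDVI endmembers), GLCM texture features (`tf`, ROI means of
#' moving-window texture maps with scene-wide per-band quantization) and
#' texture indices (`ti`, all ordered pairs of texture features). Ground
#' truth PPC is joined from the bundle's truth table.
#'
#' @param bundle A `scene_bundle`.
#' @param features Character subset of `c("ci", "vi", "fvc", "tf", "ti")`.
#' @param spec A [glcm_spec()].
#' @param red_edge Red-edge band feeding the red-edge indices
#'   (`"720"` or `"750"`).
#' @param fvc_pars An [fvc_params()].
#' @param masks Optional named list of logical masks overriding the bundle's
#'   plot masks (e.g. after inward buffering).
#' @return A tibble with one row per plot; feature provenance is attached as
#'   the `"provenance"` attribute (tibble `feature`, `type`).
#' @export
extract_features <- function(bundle, features = c("ci", "vi", "fvc", "tf", "ti"),
                             spec = glcm_spec(), red_edge = "720",
                             fvc_pars = fvc_params(), masks = NULL) {
  stopifnot(inherits(bundle, "scene_bundle"))
  features <- match.arg(features, several.ok = TRUE)
  if ("ti" %in% features && !("tf" %in% features)) {
    stop("texture indices require texture features (add \"tf\")")
  }
  masks <- masks %||% bundle$plot_masks
  plot_ids <- names(masks)
  band_lab <- paste0("R", bundle$band_nm)

  means <- purrr::map(plot_ids, function(id) {
    m <- masks[[id]]
    if (!any(m)) stop("empty mask for plot ", id)
    refl <- purrr::map_dbl(seq_along(bundle$band_nm),
                           ~ mean(bundle$reflectance[, , .x][m], na.rm = TRUE))
    dn <- purrr::map_dbl(1:3, ~ mean(bundle$rgb_dn[, , .x][m], na.rm = TRUE))
    tibble(plot_id = id, R = dn[1], G = dn[2], B = dn[3],
           !!!setNames(as.list(refl), band_lab))
  }) |> purrr::list_rbind()

  out <- means
  prov <- tibble(feature = band_lab, type = "band")
  if ("ci" %in% features) {
    out <- color_indices(out)
    prov <- bind_rows(prov, tibble(feature = ci_feature_names(), type = "ci"))
  }
  if ("vi" %in% features) {
    out <- vegetation_indices(out, red_edge = red_edge)
    prov <- bind_rows(prov, tibble(feature = vi_feature_names(), type = "vi"))
  }
  if ("fvc" %in% features) {
    nd <- ndvi_map(bundle)
    pars <- estimate_fvc_endmembers(nd, fvc_pars)
    out$FVC <- purrr::map_dbl(plot_ids, ~ fvc(nd, masks[[.x]], pars))
    prov <- bind_rows(prov, tibble(feature = "FVC", type = "fvc"))
  }
  if ("tf" %in% features) {
    maps <- purrr::map(
      setNames(seq_along(bundle$band_nm), as.character(bundle$band_nm)),
      ~ texture_maps(bundle$reflectance[, , .x], spec))
    tf_rows <- purrr::map(plot_ids,
                          ~ aggregate_textures(maps, masks[[.x]])) |>
      purrr::list_rbind()
    out <- bind_cols(out, tf_rows)
    prov <- bind_rows(prov, tibble(feature = names(tf_rows), type = "tf"))
  }
  if ("ti" %in% features) {
    before <- names(out)
    out <- texture_indices(out)
    prov <- bind_rows(prov, tibble(feature = setdiff(names(out), before),
                                   type = "ti"))
  }
  out <- bundle$truth |>
    select("plot_id", "treatment", "p_rate", "stage", "ppc_g_per_kg") |>
    left_join(out, by = "plot_id")
  attr(out, "provenance") <- prov
  out
}

#' Extract features for a multi-stage experiment
#'
#' Row-binds [extract_features()] over a named list of scene bundles (one per
#' growth stage), giving the plot-by-stage sample table used for modelling.
#'
#' @param bundles Named list of `scene_bundle` objects
#'   (e.g. from [simulate_experiment()]).
#' @inheritParams extract_features
#' @return A tibble with one row per plot per stage.
#' @export
extract_experiment <- function(bundles,
                               features = c("ci", "vi", "fvc", "tf", "ti"),
                               spec = glcm_spec(), red_edge = "720",
                               fvc_pars = fvc_params()) {
  tabs <- purrr::map(bundles, extract_features, features = features,
                     spec = spec, red_edge = red_edge, fvc_pars = fvc_pars)
  out <- purrr::list_rbind(tabs)
  attr(out, "provenance") <- attr(tabs[[1]], "provenance")
  out
}

#' Write a sample table with a provenance sidecar
#'
#' Writes the feature table as CSV and a JSON sidecar listing each column's
#' provenance tag (`ci`, `vi`, `fvc`, `tf`, `ti`, `band` or `key`).
#'
#' @param data Sample table from [extract_features()] /
#'   [extract_experiment()].
#' @param path CSV output path.
#' @return Invisibly, the paths written.
#' @export
write_sample_table <- function(data, path) {
  readr::write_csv(data, path)
  prov <- attr(data, "provenance")
  schema <- purrr::map(names(data), function(cn) {
    ty <- if (!is.null(prov) && cn %in% prov$feature) {
      prov$type[match(cn, prov$feature)]
    } else "key"
    list(column = cn, provenance = ty)
  })
  jsonlite::write_json(schema, sidecar_path(path), auto_unbox = TRUE)
  invisible(c(path, sidecar_path(path)))
}

#' Read a sample table and its provenance sidecar
#'
#' @param path CSV path written by [write_sample_table()].
#' @return Tibble with the `"provenance"` attribute restored.
#' @export
read_sample_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    schema <- jsonlite::read_json(sp, simplifyVector = TRUE)
    attr(out, "provenance") <- tibble(feature = schema$column,
                                      type = schema$provenance) |>
      filter(.data$type != "key")
  }
  out
}
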