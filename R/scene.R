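#' Field layout of the emulated phosphorus trial
#'
#' Describes the plot grid of a long-term phosphorus-rate experiment: five
#' annual P2O5 rates with three replicates each, giving fifteen plots. Plots
#' are laid out with replicates as rows and treatments as columns, separated
#' by bare-soil alleys.
#'
#' @param n_treatments Number of P treatments (default 5).
#' @param reps_per_treatment Replicates per treatment (default 3).
#' @param p_rates P2O5 application rates in kg/ha, one per treatment
#'   (default 0, 75, 120, 165, 210).
#' @param plot_shape_px Pixel extent of each plot as `c(rows, cols)`.
#' @param gsd_m Ground sample distance in metres per pixel.
#' @param gap_px Width of the bare-soil gap between plots, in pixels.
#' @return A `field_layout` object (list) with a `plots` tibble giving the
#'   pixel window and map-coordinate polygon of every plot.
#' @export
field_layout <- function(n_treatments = 5L, reps_per_treatment = 3L,
                         p_rates = c(0, 75, 120, 165, 210),
                         plot_shape_px = c(30L, 40L), gsd_m = 0.5,
                         gap_px = 4L) {
  stopifnot(n_treatments >= 1, reps_per_treatment >= 1,
            length(plot_shape_px) == 2, all(plot_shape_px >= 1),
            gsd_m > 0, gap_px >= 0)
  if (length(p_rates) != n_treatments) {
    stop("`p_rates` must have one rate per treatment (", n_treatments, ")")
  }
  pr <- as.integer(plot_shape_px[1]); pc <- as.integer(plot_shape_px[2])
  gap <- as.integer(gap_px)
  nrow_px <- reps_per_treatment * pr + (reps_per_treatment + 1L) * gap
  ncol_px <- n_treatments * pc + (n_treatments + 1L) * gap
  # geotransform: c(x_origin, dx, 0, y_origin, 0, dy); north-up, dy negative
  gt <- c(0, gsd_m, 0, nrow_px * gsd_m, 0, -gsd_m)
  treatments <- paste0("P", seq_len(n_treatments) - 1L)
  plots <- tidyr::expand_grid(trt_idx = seq_len(n_treatments),
                              rep = seq_len(reps_per_treatment)) |>
    mutate(
      treatment = treatments[.data$trt_idx],
      p_rate = p_rates[.data$trt_idx],
      plot_id = paste0(.data$treatment, "_", .data$rep),
      row0 = gap + (.data$rep - 1L) * (pr + gap) + 1L,
      col0 = gap + (.data$trt_idx - 1L) * (pc + gap) + 1L,
      row1 = .data$row0 + pr - 1L,
      col1 = .data$col0 + pc - 1L
    ) |>
    select("plot_id", "treatment", "p_rate", "rep",
           "row0", "row1", "col0", "col1")
  structure(list(n_treatments = as.integer(n_treatments),
                 reps_per_treatment = as.integer(reps_per_treatment),
                 p_rates = p_rates, plot_shape_px = c(pr, pc),
                 gsd_m = gsd_m, gap_px = gap,
                 dim = c(nrow_px, ncol_px), geotransform = gt,
                 plots = plots),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat("<field_layout> ", nrow(x$plots), " plots (",
      x$n_treatments, " treatments x ", x$reps_per_treatment,
      " reps), scene ", x$dim[1], "x", x$dim[2], " px @ ",
      x$gsd_m, " m\n", sep = "")
  invisible(x)
}

#' Canopy and reflectance model for scene simulation
#'
#' Parameterizes how plant phosphorus content (PPC), canopy cover and band
#' reflectance respond to the P application rate. PPC declines over growth
#' stages and rises with P rate following a saturating (Michaelis-type)
#' response; vegetation reflectance shifts with PPC — by default downward in
#' the visible/720 nm red-edge bands and upward at 750/840 nm, so low-P plots
#' are brighter in the visible and darker in the NIR.
#'
#' @param ppc_base_by_stage Named PPC (g/kg) at zero P for stages T1..T5;
#'   strictly decreasing by default.
#' @param ppc_gain Amplitude of the saturating PPC response to P rate (g/kg).
#' @param ppc_halfsat P rate (kg/ha) at half response.
#' @param cover_base,cover_gain Fractional canopy cover at zero P and the
#'   saturating gain with P rate; both in `[0, 1]`.
#' @param veg_spectrum,soil_spectrum Endmember reflectance per band
#'   (450, 555, 660, 720, 750, 840 nm), each in `[0, 1]`.
#' @param ppc_reflectance_slopes Per-band sensitivity of vegetation
#'   reflectance to PPC (per g/kg); negative for the first four bands and
#'   positive for 750/840 nm by default.
#' @param ppc_reference PPC (g/kg) at which the vegetation spectrum equals
#'   `veg_spectrum`.
#' @param texture_row_period_px Crop-row spatial period in pixels.
#' @param texture_amp Amplitude of the sinusoidal row modulation of cover.
#' @param texture_corr_sd,texture_corr_range_px Standard deviation and
#'   correlation length (Gaussian blur sigma, px) of the spatially correlated
#'   cover noise.
#' @param noise_sd_reflectance,noise_sd_ppc Additive Gaussian noise scales for
#'   per-pixel reflectance and per-plot PPC.
#' @param rgb_scale Reflectance mapped to digital number 255 in the rendered
#'   RGB image.
#' @param rgb_gamma Gamma exponent of the RGB rendering.
#' @return A `canopy_model` object (list).
#' @export
canopy_model <- function(ppc_base_by_stage = c(T1 = 3.6, T2 = 3.2, T3 = 2.8,
                                               T4 = 2.4, T5 = 2.0),
                         ppc_gain = 1.5, ppc_halfsat = 60,
                         cover_base = 0.45, cover_gain = 0.40,
                         veg_spectrum = c(0.045, 0.10, 0.06, 0.30, 0.45, 0.50),
                         soil_spectrum = c(0.10, 0.14, 0.18, 0.22, 0.24, 0.26),
                         ppc_reflectance_slopes = c(-0.010, -0.012, -0.012,
                                                    -0.015, 0.040, 0.050),
                         ppc_reference = 2.5,
                         texture_row_period_px = 6,
                         texture_amp = 0.08,
                         texture_corr_sd = 0.05, texture_corr_range_px = 3,
                         noise_sd_reflectance = 0.01, noise_sd_ppc = 0.08,
                         rgb_scale = 0.35, rgb_gamma = 1.0) {
  stopifnot(length(veg_spectrum) == 6, length(soil_spectrum) == 6,
            length(ppc_reflectance_slopes) == 6,
            all(veg_spectrum >= 0 & veg_spectrum <= 1),
            all(soil_spectrum >= 0 & soil_spectrum <= 1),
            cover_base >= 0, cover_base <= 1, cover_gain >= -1, cover_gain <= 1,
            ppc_halfsat > 0, noise_sd_reflectance >= 0, noise_sd_ppc >= 0,
            texture_row_period_px > 0, rgb_scale > 0, rgb_gamma > 0)
  if (is.null(names(ppc_base_by_stage))) {
    names(ppc_base_by_stage) <- ppc_stages()[seq_along(ppc_base_by_stage)]
  }
  structure(as.list(environment()), class = "canopy_model")
}

#' @export
print.canopy_model <- function(x, ...) {
  cat("<canopy_model> PPC base", paste(x$ppc_base_by_stage, collapse = "/"),
      "g/kg; gain", x$ppc_gain, "g/kg; halfsat", x$ppc_halfsat, "kg/ha\n")
  invisible(x)
}

ppc_response <- function(model, rate, stage) {
  model$ppc_base_by_stage[[stage]] +
    model$ppc_gain * rate / (rate + model$ppc_halfsat)
}

#' Simulate ground-truth plant phosphorus content for one stage
#'
#' Draws one PPC value per plot: the stage baseline plus a saturating response
#' to the plot's P rate plus Gaussian noise. Identical seeds reproduce the
#' identical table.
#'
#' @param layout A [field_layout()].
#' @param model A [canopy_model()].
#' @param stage Growth stage id, one of `"T1"`..`"T5"`.
#' @param seed Integer seed.
#' @return A tibble with one row per plot:
#'   `plot_id`, `treatment`, `p_rate`, `stage`, `ppc_g_per_kg`.
#' @export
simulate_ppc_truth <- function(layout, model = canopy_model(), stage = "T1",
                               seed = 1L) {
  stopifnot(inherits(layout, "field_layout"), inherits(model, "canopy_model"))
  valid <- names(model$ppc_base_by_stage)
  if (!is.character(stage) || length(stage) != 1 || !(stage %in% valid)) {
    stop("unknown stage ", deparse(stage), "; valid stages: ",
         paste(valid, collapse = ", "))
  }
  plots <- layout$plots
  withr::with_seed(substream_seed(seed, paste0("truth-", stage)), {
    noise <- rnorm(nrow(plots), 0, model$noise_sd_ppc)
  })
  expected <- ppc_response(model, plots$p_rate, stage)
  plots |>
    mutate(stage = .env$stage, ppc_g_per_kg = expected + noise) |>
    select("plot_id", "treatment", "p_rate", "stage", "ppc_g_per_kg")
}

# Separable Gaussian blur used to give the cover-noise field a finite
# correlation length.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  x <- apply(x, 2, pad_conv)
  t(apply(t(x), 2, pad_conv))
}

#' Render a synthetic UAV scene for one growth stage
#'
#' Builds paired six-band reflectance and RGB rasters from a ground-truth PPC
#' table. Each pixel mixes vegetation and soil endmembers by a per-pixel
#' canopy cover that carries crop-row sinusoidal modulation and spatially
#' correlated noise; the vegetation spectrum is shifted per band in proportion
#' to the plot's PPC. RGB digital numbers are rendered from the 660/555/450 nm
#' bands. The same seed gives a bit-identical bundle.
#'
#' @param layout A [field_layout()].
#' @param truth Truth tibble from [simulate_ppc_truth()] covering every plot
#'   of `layout` for a single stage.
#' @param model A [canopy_model()].
#' @param seed Integer seed.
#' @return A `scene_bundle`: list with `reflectance` (rows x cols x 6 array in
#'   `[0,1]`), `rgb_dn` (rows x cols x 3 integer array, 0-255), `band_nm`,
#'   `geotransform`, `plot_masks` (named logical matrices), `plots`
#'   (polygon table) and `truth`.
#' @export
simulate_scene <- function(layout, truth, model = canopy_model(), seed = 1L) {
  stopifnot(inherits(layout, "field_layout"), inherits(model, "canopy_model"))
  missing_ids <- setdiff(layout$plots$plot_id, truth$plot_id)
  extra_ids <- setdiff(truth$plot_id, layout$plots$plot_id)
  if (length(missing_ids) || length(extra_ids)) {
    stop("truth table does not match layout plots; missing: [",
         paste(missing_ids, collapse = ", "), "] unexpected: [",
         paste(extra_ids, collapse = ", "), "]")
  }
  if (length(unique(truth$stage)) != 1) stop("truth must cover a single stage")
  nr <- layout$dim[1]; nc <- layout$dim[2]
  nb <- 6L
  refl <- array(NA_real_, c(nr, nc, nb))
  withr::with_seed(substream_seed(seed, paste0("scene-", truth$stage[1])), {
    for (b in seq_len(nb)) refl[, , b] <- model$soil_spectrum[b]
    masks <- list()
    for (i in seq_len(nrow(layout$plots))) {
      p <- layout$plots[i, ]
      rows <- p$row0:p$row1; cols <- p$col0:p$col1
      ppc <- truth$ppc_g_per_kg[truth$plot_id == p$plot_id]
      rate <- p$p_rate
      cover0 <- clamp01(model$cover_base +
                          model$cover_gain * rate / (rate + model$ppc_halfsat))
      phase <- runif(1, 0, 2 * pi)
      rowgrid <- matrix(rows, length(rows), length(cols))
      modn <- model$texture_amp *
        sin(2 * pi * rowgrid / model$texture_row_period_px + phase)
      if (model$texture_corr_sd > 0) {
        w <- matrix(rnorm(length(rows) * length(cols)),
                    length(rows), length(cols))
        w <- gauss_blur(w, model$texture_corr_range_px)
        sw <- sd(as.numeric(w))
        if (sw > 0) w <- w / sw * model$texture_corr_sd
        modn <- modn + w
      }
      cover_px <- clamp01(cover0 * (1 + modn))
      veg_adj <- clamp01(model$veg_spectrum +
                           model$ppc_reflectance_slopes *
                           (ppc - model$ppc_reference))
      for (b in seq_len(nb)) {
        refl[rows, cols, b] <- cover_px * veg_adj[b] +
          (1 - cover_px) * model$soil_spectrum[b]
      }
      m <- matrix(FALSE, nr, nc)
      m[rows, cols] <- TRUE
      masks[[p$plot_id]] <- m
    }
    if (model$noise_sd_reflectance > 0) {
      refl <- refl + array(rnorm(length(refl), 0, model$noise_sd_reflectance),
                           dim(refl))
    }
  })
  refl <- array(clamp01(refl), dim(refl))
  # RGB from the red/green/blue reflectance bands of the same latent canopy
  rgb <- array(0L, c(nr, nc, 3L))
  for (k in seq_len(3)) {
    src <- c(3L, 2L, 1L)[k]  # 660, 555, 450 nm
    dn <- clamp01(refl[, , src] / model$rgb_scale)^(1 / model$rgb_gamma)
    rgb[, , k] <- as.integer(round(255 * dn))
  }
  polys <- plot_polygons(layout)
  structure(list(reflectance = refl, rgb_dn = rgb,
                 band_nm = ppc_band_nm(), geotransform = layout$geotransform,
                 plot_masks = masks, plots = polys, truth = truth,
                 gsd_m = layout$gsd_m),
            class = "scene_bundle")
}

# Map-coordinate rectangles of every plot (list-column of 4x2 rings).
plot_polygons <- function(layout) {
  gt <- layout$geotransform
  layout$plots |>
    mutate(polygon = purrr::pmap(list(.data$row0, .data$row1,
                                      .data$col0, .data$col1),
                                 function(r0, r1, c0, c1) {
      x0 <- gt[1] + (c0 - 1) * gt[2]; x1 <- gt[1] + c1 * gt[2]
      y0 <- gt[4] + (r0 - 1) * gt[6]; y1 <- gt[4] + r1 * gt[6]
      cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
    }))
}

#' @export
print.scene_bundle <- function(x, ...) {
  d <- dim(x$reflectance)
  cat("<scene_bundle> ", d[1], "x", d[2], " px, ", d[3], " bands (",
      paste(x$band_nm, collapse = "/"), " nm), ", length(x$plot_masks),
      " plots, stage ", x$truth$stage[1], "\n", sep = "")
  invisible(x)
}

#' Simulate the full multi-stage experiment
#'
#' Convenience wrapper generating one scene bundle per growth stage with
#' deterministic per-stage seeds derived from a single seed.
#'
#' @inheritParams simulate_scene
#' @param stages Character vector of stage ids (default all five).
#' @return Named list of `scene_bundle` objects.
#' @export
simulate_experiment <- function(layout = field_layout(),
                                model = canopy_model(),
                                stages = ppc_stages(), seed = 1L) {
  purrr::map(setNames(stages, stages), function(st) {
    truth <- simulate_ppc_truth(layout, model, st, seed)
    simulate_scene(layout, truth, model, seed)
  })
}

#' Write a scene bundle to disk
#'
#' Writes the six-band reflectance raster as a multi-page float32 TIFF and the
#' RGB digital numbers as an 8-bit TIFF, each with a JSON sidecar holding the
#' geotransform and band metadata, plus plot polygons as GeoJSON (with
#' `plot_id`/`treatment` properties) and the truth table as CSV.
#'
#' @param bundle A `scene_bundle`.
#' @param dir Output directory (created if needed).
#' @return A tibble manifest with `file`, `type` and `md5` columns.
#' @export
write_scene <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  refl_path <- file.path(dir, "reflectance.tif")
  bands <- purrr::map(seq_len(dim(bundle$reflectance)[3]),
                      ~ bundle$reflectance[, , .x])
  tiff::writeTIFF(bands, refl_path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(geotransform = bundle$geotransform,
         band_names = as.character(bundle$band_nm),
         units = "surface reflectance", gsd_m = bundle$gsd_m),
    sidecar_path(refl_path), auto_unbox = TRUE, digits = NA)
  rgb_path <- file.path(dir, "rgb.tif")
  tiff::writeTIFF(bundle$rgb_dn / 255, rgb_path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(geotransform = bundle$geotransform,
         band_names = c("R", "G", "B"), units = "digital number",
         gsd_m = bundle$gsd_m),
    sidecar_path(rgb_path), auto_unbox = TRUE, digits = NA)
  roi_path <- file.path(dir, "plots.geojson")
  write_plot_rois(bundle$plots, roi_path)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(bundle$truth, truth_path)
  files <- c(refl_path, sidecar_path(refl_path), rgb_path,
             sidecar_path(rgb_path), roi_path, truth_path)
  tibble(file = files,
         type = c("reflectance", "reflectance_meta", "rgb", "rgb_meta",
                  "rois", "truth"),
         md5 = unname(tools::md5sum(files)))
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a scene bundle back from disk
#'
#' Inverse of [write_scene()]: reads the rasters, sidecars, ROIs and truth
#' table written for one stage. Plot masks are re-rasterized from the ROI
#' polygons.
#'
#' @param dir Directory written by [write_scene()].
#' @return A `scene_bundle`.
#' @export
read_scene <- function(dir) {
  refl <- read_band_stack(file.path(dir, "reflectance.tif"),
                          as.character(ppc_band_nm()))
  rgb <- read_band_stack(file.path(dir, "rgb.tif"), c("R", "G", "B"))
  rois <- read_plot_rois(file.path(dir, "plots.geojson"))
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  d <- dim(refl$pixels[[1]])
  refl_arr <- array(NA_real_, c(d, length(refl$pixels)))
  for (b in seq_along(refl$pixels)) refl_arr[, , b] <- refl$pixels[[b]]
  rgb_arr <- array(0L, c(d, 3L))
  for (b in 1:3) rgb_arr[, , b] <- as.integer(round(rgb$pixels[[b]] * 255))
  masks <- purrr::map(setNames(rois, purrr::map_chr(rois, "plot_id")),
                      ~ rasterize_roi(.x, refl$geotransform, d))
  plots <- tibble(plot_id = purrr::map_chr(rois, "plot_id"),
                  treatment = purrr::map_chr(rois, "treatment"),
                  polygon = purrr::map(rois, "polygon"))
  structure(list(reflectance = refl_arr, rgb_dn = rgb_arr,
                 band_nm = ppc_band_nm(), geotransform = refl$geotransform,
                 plot_masks = masks, plots = plots,
                 truth = truth, gsd_m = refl$geotransform[2]),
            class = "scene_bundle")
}

#' Quick-look plot of a scene
#'
#' Renders the RGB digital numbers of a scene bundle with ggplot2.
#'
#' @param bundle A `scene_bundle`.
#' @return A ggplot object.
#' @export
plot_scene <- function(bundle) {
  stopifnot(inherits(bundle, "scene_bundle"))
  d <- dim(bundle$rgb_dn)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2])) |>
    mutate(fill = grDevices::rgb(bundle$rgb_dn[, , 1][cbind(row, col)] / 255,
                                 bundle$rgb_dn[, , 2][cbind(row, col)] / 255,
                                 bundle$rgb_dn[, , 3][cbind(row, col)] / 255))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Synthetic scene, stage",
                                bundle$truth$stage[1])) +
    ggplot2::theme_minimal()
}
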