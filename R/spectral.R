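safe_div <- function(num, den) {
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Colour indices from RGB digital numbers
#'
#' Appends the fourteen colour indices to a data frame of per-plot mean RGB
#' digital numbers: the raw channels `R`, `G`, `B`; the normalized shares
#' `r = R/(R+G+B)`, `g`, `b`; and `BGI = b/g`, `BRI = b/r`, `GRI = g/r`,
#' `CI_GRVI = (g-r)/(g+r)`, `VARI = (g-r)/(g+r-b)`,
#' `MGRVI = (g^2-r^2)/(g^2+r^2)`, `RGBVI = (g^2-r*b)/(g^2+r*b)` and
#' `TGI = -0.5*(190*(r-g) - 120*(r+b))`. Two green-red ratio indices exist in
#' the field; the normalized-difference one computed from RGB shares is named
#' `CI_GRVI` here to keep it distinct from the reflectance ratio
#' `GRVI_ratio` of [vegetation_indices()].
#'
#' Undefined ratios (zero denominators) become `NA` rather than infinities.
#' With `strict_printed_formulas = FALSE`, `TGI` uses the `(r - b)` variant
#' found in part of the literature instead of `(r + b)`.
#'
#' @param data Data frame with numeric columns `R`, `G`, `B` (mean DN,
#'   0-255).
#' @param strict_printed_formulas Use the index formulas exactly as commonly
#'   tabulated (default `TRUE`).
#' @return The input as a tibble with the colour-index columns appended.
#' @export
color_indices <- function(data, strict_printed_formulas = TRUE) {
  stopifnot(all(c("R", "G", "B") %in% names(data)))
  data <- as_tibble(data)
  tot <- data$R + data$G + data$B
  if (any(tot <= 0, na.rm = TRUE)) {
    warning("rows with non-positive R+G+B yield NA colour indices")
  }
  r <- safe_div(data$R, tot); g <- safe_div(data$G, tot)
  b <- safe_div(data$B, tot)
  tgi <- if (strict_printed_formulas) {
    -0.5 * (190 * (r - g) - 120 * (r + b))
  } else {
    -0.5 * (190 * (r - g) - 120 * (r - b))
  }
  data |>
    mutate(r = r, g = g, b = b,
           BGI = safe_div(b, g),
           BRI = safe_div(b, r),
           GRI = safe_div(g, r),
           CI_GRVI = safe_div(g - r, g + r),
           VARI = safe_div(g - r, g + r - b),
           MGRVI = safe_div(g^2 - r^2, g^2 + r^2),
           RGBVI = safe_div(g^2 - r * b, g^2 + r * b),
           TGI = tgi)
}

ci_feature_names <- function() {
  c("R", "G", "B", "r", "g", "b", "BGI", "BRI", "GRI", "CI_GRVI", "VARI",
    "MGRVI", "RGBVI", "TGI")
}

#' Vegetation indices from multispectral reflectance
#'
#' Appends the twelve vegetation indices to a data frame of per-plot mean
#' band reflectances named `R450`, `R555`, `R660`, `R720`, `R750`, `R840`:
#' `NDVI`, `GNDVI`, `BNDVI`, `NDRE`, `MTCI`, `DVI`, `RVI`,
#' `GRVI_ratio = R840/R555`, `CI_red_edge = R840/RE - 1`,
#' `EVI = 2.5*(NIR-RED)/(NIR + 6*RED - 7.5*BLUE + 1)`,
#' `OSAVI = 1.16*(NIR-RED)/(NIR+RED+0.16)` and
#' `ExG = 2*(GREEN-RED-BLUE)/(GREEN+RED+BLUE)` (on reflectance). The camera
#' carries two red-edge bands; `red_edge` selects which one feeds the
#' red-edge indices (default 720 nm).
#'
#' @param data Data frame with the six reflectance columns.
#' @param red_edge `"720"` or `"750"`; band used as the red edge.
#' @return The input as a tibble with the vegetation-index columns appended.
#' @export
vegetation_indices <- function(data, red_edge = c("720", "750")) {
  red_edge <- match.arg(red_edge)
  need <- paste0("R", ppc_band_nm())
  stopifnot(all(need %in% names(data)))
  data <- as_tibble(data)
  blue <- data$R450; green <- data$R555; red <- data$R660
  re <- data[[paste0("R", red_edge)]]; nir <- data$R840
  data |>
    mutate(NDVI = safe_div(nir - red, nir + red),
           GNDVI = safe_div(nir - green, nir + green),
           BNDVI = safe_div(nir - blue, nir + blue),
           NDRE = safe_div(nir - re, nir + re),
           MTCI = safe_div(nir - re, re - red),
           DVI = nir - red,
           RVI = safe_div(nir, red),
           GRVI_ratio = safe_div(nir, green),
           CI_red_edge = safe_div(nir, re) - 1,
           EVI = safe_div(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1),
           OSAVI = safe_div((1 + 0.16) * (nir - red), nir + red + 0.16),
           ExG = safe_div(2 * (green - red - blue), green + red + blue))
}

vi_feature_names <- function() {
  c("NDVI", "GNDVI", "BNDVI", "NDRE", "MTCI", "DVI", "RVI", "GRVI_ratio",
    "CI_red_edge", "EVI", "OSAVI", "ExG")
}

#' Per-pixel NDVI map
#'
#' `(R840 - R660) / (R840 + R660)` per pixel; pixels whose band sum is zero
#' are marked missing.
#'
#' @param x A `scene_bundle`, a [band_stack()] carrying bands `"660"` and
#'   `"840"`, or a list with matrices `red` and `nir`.
#' @return Numeric matrix of NDVI values in `[-1, 1]` (NA where undefined).
#' @export
ndvi_map <- function(x) {
  if (inherits(x, "scene_bundle")) {
    red <- x$reflectance[, , match(660L, x$band_nm)]
    nir <- x$reflectance[, , match(840L, x$band_nm)]
  } else if (inherits(x, "band_stack")) {
    if (!all(c("660", "840") %in% x$band_names)) {
      stop("band_stack must carry bands 660 and 840")
    }
    red <- x$pixels[["660"]]; nir <- x$pixels[["840"]]
  } else if (is.list(x) && all(c("red", "nir") %in% names(x))) {
    red <- x$red; nir <- x$nir
  } else stop("cannot extract 660/840 nm bands from input")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Fractional vegetation cover parameters
#'
#' Soil and vegetation NDVI endmembers for the dimidiate (two-endmember)
#' pixel model. When endmembers are not supplied they are estimated from the
#' scene-wide NDVI distribution at the `lower_pct`/`upper_pct` percentiles
#' (defaults 5 and 95).
#'
#' @param ndvi_soil,ndvi_veg Endmember NDVI values (`ndvi_soil < ndvi_veg`).
#' @param lower_pct,upper_pct Percentiles used when estimating endmembers.
#' @return An `fvc_params` object.
#' @export
fvc_params <- function(ndvi_soil = NULL, ndvi_veg = NULL,
                       lower_pct = 5, upper_pct = 95) {
  if (!is.null(ndvi_soil) && !is.null(ndvi_veg) && ndvi_soil >= ndvi_veg) {
    stop("ndvi_soil must be below ndvi_veg")
  }
  structure(list(ndvi_soil = ndvi_soil, ndvi_veg = ndvi_veg,
                 lower_pct = lower_pct, upper_pct = upper_pct),
            class = "fvc_params")
}

estimate_fvc_endmembers <- function(ndvi, params) {
  if (is.null(params$ndvi_soil) || is.null(params$ndvi_veg)) {
    qs <- quantile(ndvi, c(params$lower_pct, params$upper_pct) / 100,
                   na.rm = TRUE, names = FALSE)
    params$ndvi_soil <- params$ndvi_soil %||% qs[1]
    params$ndvi_veg <- params$ndvi_veg %||% qs[2]
  }
  if (!(params$ndvi_veg > params$ndvi_soil) ||
      (params$ndvi_veg - params$ndvi_soil) < 1e-8) {
    stop("degenerate NDVI distribution: vegetation and soil endmembers ",
         "coincide (soil = ", format(params$ndvi_soil),
         ", veg = ", format(params$ndvi_veg), ")")
  }
  params
}

#' Fractional vegetation cover of a plot
#'
#' Dimidiate pixel model: per-pixel
#' `(NDVI - NDVI_soil) / (NDVI_veg - NDVI_soil)` clipped to `[0, 1]`, then
#' averaged over the ROI. Endmembers default to scene-wide NDVI percentiles
#' (see [fvc_params()]).
#'
#' @param ndvi NDVI matrix (scene-wide, used for endmember estimation).
#' @param roi Logical mask matrix or a [plot_roi()] plus `geotransform`
#'   attribute handling via [zonal_mean()] is not needed here: pass a mask.
#' @param params An [fvc_params()].
#' @return FVC value in `[0, 1]`.
#' @export
fvc <- function(ndvi, roi, params = fvc_params()) {
  params <- estimate_fvc_endmembers(ndvi, params)
  f <- clamp01((ndvi - params$ndvi_soil) / (params$ndvi_veg - params$ndvi_soil))
  mask <- if (is.logical(roi)) roi else stop("roi must be a logical mask")
  if (!any(mask)) stop("empty ROI")
  mean(f[mask], na.rm = TRUE)
}
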