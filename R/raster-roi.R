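#' Read a multi-band raster with its sidecar metadata
#'
#' Reads a multi-page (or multi-channel) TIFF and its JSON sidecar (written by
#' [write_scene()] or compatible tooling) carrying the geotransform and band
#' names. Bands are returned in the order of `expected_bands`.
#'
#' @param path TIFF path; the sidecar is `<path minus extension>.json`.
#' @param expected_bands Character vector of band labels the file must carry.
#' @return A `band_stack`: list with `pixels` (named list of matrices),
#'   `band_names` and `geotransform`.
#' @export
read_band_stack <- function(path, expected_bands) {
  if (!file.exists(path)) stop("raster not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- purrr::flatten(purrr::map(pages, function(pg) {
    if (length(dim(pg)) == 3) {
      purrr::map(seq_len(dim(pg)[3]), ~ pg[, , .x])
    } else list(pg)
  }))
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  found <- meta$band_names %||% as.character(seq_along(mats))
  if (length(mats) != length(expected_bands)) {
    stop("band count mismatch in ", path, ": expected ",
         length(expected_bands), " (", paste(expected_bands, collapse = ", "),
         "), found ", length(mats), " (", paste(found, collapse = ", "), ")")
  }
  names(mats) <- found
  if (!setequal(found, expected_bands)) {
    stop("band labels in ", path, " (", paste(found, collapse = ", "),
         ") do not match expected (", paste(expected_bands, collapse = ", "),
         ")")
  }
  mats <- mats[expected_bands]
  gt <- meta$geotransform %||% c(0, 1, 0, nrow(mats[[1]]), 0, -1)
  band_stack(mats, expected_bands, gt)
}

#' Construct a band stack in memory
#'
#' @param pixels Named list of numeric matrices (one per band) or a 3-D array.
#' @param band_names Ordered band labels.
#' @param geotransform Affine pixel-to-map transform
#'   `c(x0, dx, 0, y0, 0, dy)`.
#' @return A `band_stack` object.
#' @export
band_stack <- function(pixels, band_names = names(pixels),
                       geotransform = c(0, 1, 0, NA, 0, -1)) {
  if (is.array(pixels) && length(dim(pixels)) == 3) {
    pixels <- purrr::map(seq_len(dim(pixels)[3]), ~ pixels[, , .x])
  }
  stopifnot(is.list(pixels), length(pixels) >= 1)
  dims <- purrr::map(pixels, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    stop("all bands must share the same shape")
  }
  if (is.null(band_names)) band_names <- as.character(seq_along(pixels))
  if (anyDuplicated(band_names)) stop("band names must be unique")
  if (is.na(geotransform[4])) geotransform[4] <- nrow(pixels[[1]])
  names(pixels) <- band_names
  structure(list(pixels = pixels, band_names = band_names,
                 geotransform = geotransform),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat("<band_stack> ", d[1], "x", d[2], " px, bands: ",
      paste(x$band_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot region of interest
#'
#' A plot ROI is a map-coordinate polygon ring with identity attributes; a
#' boolean pixel mask is derived on demand by [rasterize_roi()].
#'
#' @param plot_id Plot label.
#' @param treatment Treatment label.
#' @param polygon Numeric n x 2 matrix of ring vertices (x, y), open ring.
#' @return A `plot_roi` object.
#' @export
plot_roi <- function(plot_id, treatment, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  if (abs(polygon_area(polygon)) <= 0) stop("polygon has zero area")
  structure(list(plot_id = plot_id, treatment = treatment, polygon = polygon),
            class = "plot_roi")
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  i2 <- c(seq_len(nrow(ring))[-1], 1L)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

#' Shrink a plot ROI inward
#'
#' Offsets every edge of a convex ring inward by `distance_m` and clips the
#' ring against the resulting half-planes, removing edge disturbances (soil
#' alleys, shadows, weeds) from the plot boundary before aggregation.
#'
#' @param roi A [plot_roi()].
#' @param distance_m Non-negative inward distance in map units (metres).
#' @return The buffered `plot_roi`.
#' @export
buffer_inward <- function(roi, distance_m = 0.75) {
  stopifnot(inherits(roi, "plot_roi"), distance_m >= 0)
  if (distance_m == 0) return(roi)
  ring <- roi$polygon
  if (polygon_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]  # CCW
  out <- ring
  nv <- nrow(ring)
  for (i in seq_len(nv)) {
    p <- ring[i, ]; q <- ring[if (i == nv) 1L else i + 1L, ]
    d <- q - p; len <- sqrt(sum(d^2))
    if (len == 0) next
    nrm <- c(-d[2], d[1]) / len  # inward (left) normal of a CCW ring
    anchor <- p + distance_m * nrm
    out <- clip_halfplane(out, anchor, nrm)
    if (is.null(out) || nrow(out) < 3) {
      stop("inward buffer of ", distance_m,
           " erases plot ", roi$plot_id, "; use a smaller distance")
    }
  }
  if (abs(polygon_area(out)) <= 1e-12) {
    stop("inward buffer of ", distance_m, " erases plot ", roi$plot_id,
         "; use a smaller distance")
  }
  plot_roi(roi$plot_id, roi$treatment, out)
}

# Sutherland-Hodgman clip of a ring against the half-plane
# dot(z - anchor, normal) >= 0.
clip_halfplane <- function(ring, anchor, normal) {
  nv <- nrow(ring)
  sig <- (ring[, 1] - anchor[1]) * normal[1] +
    (ring[, 2] - anchor[2]) * normal[2]
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    a_in <- sig[i] >= -1e-12; b_in <- sig[j] >= -1e-12
    if (a_in) out <- rbind(out, ring[i, ])
    if (xor(a_in, b_in)) {
      t <- sig[i] / (sig[i] - sig[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  if (nrow(out) == 0) return(NULL)
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
  out[keep, , drop = FALSE]
}

#' Rasterize a plot ROI to a boolean mask
#'
#' A pixel belongs to the mask when its centre falls inside the polygon
#' (pixel-centre rule, row-major, 1-based rows/cols).
#'
#' @param roi A [plot_roi()].
#' @param geotransform Raster geotransform `c(x0, dx, 0, y0, 0, dy)`.
#' @param dim Raster dimensions `c(rows, cols)`.
#' @return Logical matrix of the raster shape.
#' @export
rasterize_roi <- function(roi, geotransform, dim) {
  gt <- geotransform
  xs <- gt[1] + (seq_len(dim[2]) - 0.5) * gt[2]
  ys <- gt[4] + (seq_len(dim[1]) - 0.5) * gt[6]
  pts <- cbind(rep(xs, each = dim[1]), rep(ys, times = dim[2]))
  ring <- roi$polygon
  bnd <- rbind(ring, ring[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, pts)
  matrix(inside, dim[1], dim[2])
}

#' Per-plot mean of each band over an ROI
#'
#' Arithmetic mean of the masked pixels of every band; missing pixels are
#' excluded from both numerator and denominator.
#'
#' @param stack A [band_stack()].
#' @param roi A [plot_roi()] or a logical mask matrix of the raster shape.
#' @return A tibble with one row per band: `band`, `mean`.
#' @export
zonal_mean <- function(stack, roi) {
  stopifnot(inherits(stack, "band_stack"))
  d <- dim(stack$pixels[[1]])
  mask <- if (inherits(roi, "plot_roi")) {
    rasterize_roi(roi, stack$geotransform, d)
  } else roi
  stopifnot(is.logical(mask), all(dim(mask) == d))
  if (!any(mask)) stop("ROI does not overlap the raster")
  tibble(band = stack$band_names,
         mean = unname(purrr::map_dbl(stack$pixels,
                                      ~ mean(.x[mask], na.rm = TRUE))))
}

# ---- GeoJSON plot ROIs ------------------------------------------------------

write_plot_rois <- function(plots, path) {
  feats <- purrr::pmap(list(plots$plot_id, plots$treatment, plots$polygon),
                       function(id, trt, ring) {
    ring_closed <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plot_id = id, treatment = trt),
         geometry = list(type = "Polygon",
                         coordinates = list(
                           purrr::map(seq_len(nrow(ring_closed)),
                                      ~ as.numeric(ring_closed[.x, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot ROIs from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of polygons with `plot_id` and
#'   `treatment` properties.
#' @return List of [plot_roi()] objects.
#' @export
read_plot_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  gj <- jsonlite::read_json(path)
  purrr::map(gj$features, function(f) {
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ as.numeric(unlist(.x))))
    # drop the closing vertex
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    plot_roi(f$properties$plot_id, f$properties$treatment, ring)
  })
}
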