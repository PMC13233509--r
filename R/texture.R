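#' GLCM extraction contract
#'
#' Fixes the configuration of grey-level co-occurrence texture extraction:
#' quantization to `levels` grey levels, an odd moving `window`, four
#' directions (0, 45, 90, 135 degrees) at 1-pixel offset, symmetric
#' co-occurrence counting, directional averaging and natural-log entropy.
#'
#' @param levels Grey levels after quantization (default 64).
#' @param window Odd moving-window size in pixels (default 3).
#' @param symmetric Count each pair in both orders (default `TRUE`; the
#'   implemented statistics assume it).
#' @return A `glcm_spec` object.
#' @export
glcm_spec <- function(levels = 64L, window = 3L, symmetric = TRUE) {
  stopifnot(levels >= 2, window >= 3, window %% 2 == 1, isTRUE(symmetric))
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 symmetric = TRUE,
                 offsets = list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                                `90` = c(-1L, 0L), `135` = c(-1L, -1L))),
            class = "glcm_spec")
}

#' Quantize a raster to grey-level bins
#'
#' Linear min-max scaling to integer bins `0 .. levels-1`; the range minimum
#' maps to bin 0 and the maximum to `levels - 1`. By default the range is the
#' finite scene-wide range of the band, which keeps bin meanings (and hence
#' MEA/VAR texture values) comparable across plots; pass `range` to fix it
#' externally. A constant band maps entirely to bin 0 with a warning.
#'
#' @param band Numeric matrix.
#' @param spec A [glcm_spec()] (only `levels` is used).
#' @param range Optional `c(min, max)` quantization range.
#' @return Integer matrix of bins (NA preserved).
#' @export
quantize <- function(band, spec = glcm_spec(), range = NULL) {
  levels <- spec$levels
  fin <- band[is.finite(band)]
  if (length(fin) == 0) stop("band has no finite values")
  if (is.null(range)) range <- c(min(fin), max(fin))
  lo <- range[1]; hi <- range[2]
  out <- matrix(NA_integer_, nrow(band), ncol(band))
  if (hi <= lo) {
    warning("constant band: all pixels quantized to bin 0")
    out[is.finite(band)] <- 0L
    return(out)
  }
  bins <- floor((band - lo) / (hi - lo) * levels)
  bins <- pmin(pmax(bins, 0), levels - 1)
  out[is.finite(band)] <- as.integer(bins[is.finite(band)])
  out
}

#' GLCM statistics of a single patch
#'
#' Builds, for each of the four directions, a symmetric normalized
#' co-occurrence table from the valid pixel pairs of the quantized patch and
#' computes the eight texture statistics: `Mea` (mean), `Var` (variance),
#' `Hom` (homogeneity), `Con` (contrast), `Dis` (dissimilarity), `Ent`
#' (entropy, natural log, with `0*log 0 = 0`), `Sem` (second/angular moment)
#' and `Cor` (correlation; 0 when the table variance is zero). The four
#' directional values are averaged; directions without valid pairs are
#' excluded.
#'
#' @param patch Integer matrix of grey bins (e.g. from [quantize()]), at
#'   least 2x2.
#' @param spec A [glcm_spec()].
#' @return Named numeric vector of the eight statistics (all NA when no
#'   direction has a valid pair).
#' @export
glcm_stats <- function(patch, spec = glcm_spec()) {
  stopifnot(is.matrix(patch), nrow(patch) >= 2 || ncol(patch) >= 2)
  storage.mode(patch) <- "integer"
  per_dir <- purrr::map(spec$offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    nr <- nrow(patch); nc <- ncol(patch)
    rows <- seq_len(nr); cols <- seq_len(nc)
    r1 <- rows[rows + dr >= 1 & rows + dr <= nr]
    c1 <- cols[cols + dc >= 1 & cols + dc <= nc]
    if (length(r1) == 0 || length(c1) == 0) return(NULL)
    a <- patch[r1, c1, drop = FALSE]
    b <- patch[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NULL)
    i <- c(a[ok], b[ok]); j <- c(b[ok], a[ok])  # symmetric
    n <- length(i)
    p <- as.numeric(table(i * 1e6 + j)) / n
    stopifnot(abs(sum(p) - 1) < 1e-9)
    mea <- mean(i)
    v <- mean((i - mea)^2)
    c(Mea = mea, Var = v,
      Hom = mean(1 / (1 + (i - j)^2)),
      Con = mean((i - j)^2),
      Dis = mean(abs(i - j)),
      Ent = -sum(p * log(p)),
      Sem = sum(p^2),
      Cor = if (v > 1e-12) mean((i - mea) * (j - mea)) / v else 0)
  })
  per_dir <- purrr::compact(per_dir)
  if (length(per_dir) == 0) {
    return(setNames(rep(NA_real_, 8),
                    c("Mea", "Var", "Hom", "Con", "Dis", "Ent", "Sem", "Cor")))
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

#' Moving-window texture maps of one band
#'
#' Quantizes the band ([quantize()]) and computes the eight GLCM statistics
#' of the centred window at every pixel. Border pixels whose window is
#' incomplete are missing (no padding).
#'
#' @param band Numeric matrix of reflectance.
#' @param spec A [glcm_spec()].
#' @param range Optional quantization range passed to [quantize()].
#' @return Named list of eight matrices (`Mea` .. `Cor`).
#' @export
texture_maps <- function(band, spec = glcm_spec(), range = NULL) {
  if (nrow(band) < spec$window || ncol(band) < spec$window) {
    stop("raster (", nrow(band), "x", ncol(band),
         ") smaller than the moving window (", spec$window, ")")
  }
  q <- quantize(band, spec, range)
  cpp_glcm_maps(q, spec$window)
}

tf_stat_names <- function() {
  c("Mea", "Var", "Hom", "Con", "Dis", "Ent", "Sem", "Cor")
}

#' Aggregate texture maps over a plot ROI
#'
#' ROI mean of every texture map of every band, named in the
#' `<band>-<Stat>` convention (e.g. `450-Mea` is the mean texture of the
#' 450 nm band).
#'
#' @param maps_by_band Named list (band label -> list of eight stat maps as
#'   returned by [texture_maps()]).
#' @param mask Logical ROI mask matrix.
#' @return One-row tibble with `8 * n_bands` texture-feature columns.
#' @export
aggregate_textures <- function(maps_by_band, mask) {
  if (!any(mask)) stop("empty ROI")
  vals <- purrr::imap(maps_by_band, function(maps, band) {
    v <- purrr::map_dbl(maps[tf_stat_names()], ~ mean(.x[mask], na.rm = TRUE))
    setNames(v, paste0(band, "-", tf_stat_names()))
  })
  as_tibble(as.list(unlist(unname(vals))))
}

tf_col_pattern <- function() {
  "^[0-9]+-(Mea|Var|Hom|Con|Dis|Ent|Sem|Cor)$"
}

#' Texture indices from texture features
#'
#' For ordered pairs of texture features `(T1, T2)` drawn from any band and
#' statistic, computes the three texture-index families
#' `NDTI = (T1 - T2)/(T1 + T2)`, `RTI = T1/T2` and `DTI = T1 - T2`, appended
#' as columns named e.g. `DTI(450-Ent,750-Mea)`. Under the default
#' `all_ordered` policy every ordered pair of distinct features is
#' enumerated (`k * (k-1)` pairs per family for `k` features); a two-column
#' data frame of feature names restricts the pairs (self-pairs allowed).
#' Zero denominators yield `NA`.
#'
#' @param data Data frame containing texture-feature columns (recognized by
#'   the `<band>-<Stat>` naming or listed in `tf_cols`).
#' @param pairs `"all_ordered"` or a data frame with columns `t1`, `t2`.
#' @param tf_cols Optional character vector naming the texture columns.
#' @return The input tibble with the texture-index columns appended.
#' @export
texture_indices <- function(data, pairs = "all_ordered", tf_cols = NULL) {
  data <- as_tibble(data)
  if (is.null(tf_cols)) {
    tf_cols <- grep(tf_col_pattern(), names(data), value = TRUE)
  }
  if (length(tf_cols) == 0) stop("no texture-feature columns found")
  X <- as.matrix(data[tf_cols])
  if (is.data.frame(pairs)) {
    ia <- match(pairs[[1]], tf_cols); ib <- match(pairs[[2]], tf_cols)
    if (anyNA(ia) || anyNA(ib)) {
      bad <- unique(c(pairs[[1]][is.na(ia)], pairs[[2]][is.na(ib)]))
      stop("unknown texture features in pair list: ",
           paste(bad, collapse = ", "))
    }
  } else if (identical(pairs, "all_ordered")) {
    k <- length(tf_cols)
    if (k < 2) stop("need at least two texture features for ordered pairs")
    grid <- expand.grid(ib = seq_len(k), ia = seq_len(k))
    grid <- grid[grid$ia != grid$ib, ]
    # order: for each T1 (ia) sweep T2 (ib)
    grid <- grid[order(grid$ia, grid$ib), ]
    ia <- grid$ia; ib <- grid$ib
  } else stop("pairs must be \"all_ordered\" or a data frame of name pairs")
  T1 <- X[, ia, drop = FALSE]; T2 <- X[, ib, drop = FALSE]
  ndti <- (T1 - T2) / (T1 + T2); ndti[!is.finite(ndti)] <- NA_real_
  rti <- T1 / T2; rti[!is.finite(rti)] <- NA_real_
  dti <- T1 - T2
  pair_lab <- paste0("(", tf_cols[ia], ",", tf_cols[ib], ")")
  colnames(ndti) <- paste0("NDTI", pair_lab)
  colnames(rti) <- paste0("RTI", pair_lab)
  colnames(dti) <- paste0("DTI", pair_lab)
  bind_cols(data, as_tibble(ndti), as_tibble(rti), as_tibble(dti))
}

ti_col_pattern <- function() "^(NDTI|RTI|DTI)\\("
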