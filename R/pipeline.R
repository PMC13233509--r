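#' Declarative configuration of a full pipeline run
#'
#' One object drives simulate -> extract -> select -> model. Every random
#' stage derives its own substream seed deterministically from the single
#' global `seed`, so one number reproduces the whole run.
#'
#' @param out_dir Output directory of the run.
#' @param seed Global integer seed.
#' @param stages Growth stages to simulate/extract.
#' @param layout A [field_layout()].
#' @param canopy A [canopy_model()].
#' @param features Feature-family toggles, subset of
#'   `c("ci","vi","fvc","tf","ti")`.
#' @param glcm A [glcm_spec()].
#' @param red_edge Red-edge band (`"720"` or `"750"`).
#' @param buffer_m Inward ROI buffer distance in metres (default 0.75, the
#'   midpoint of the usual 0.5-1 m range).
#' @param selection List: `method` (`"pearson"`, `"rf_importance"` or
#'   `"relief"`), `top_k`, and method-specific parameters.
#' @param model A [ppc_model_config()] or list of them (one per family to
#'   evaluate).
#' @param split_ratio Training fraction.
#' @param stratify_by Optional stratification column.
#' @param sizes Optional subset sizes for a selection sweep.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, seed = 1L, stages = ppc_stages(),
                       layout = field_layout(), canopy = canopy_model(),
                       features = c("ci", "vi", "fvc", "tf", "ti"),
                       glcm = glcm_spec(), red_edge = "720",
                       buffer_m = 0.75,
                       selection = list(method = "rf_importance", top_k = 10),
                       model = list(ppc_model_config("rf"),
                                    ppc_model_config("svm"),
                                    ppc_model_config("knn")),
                       split_ratio = 0.75, stratify_by = NULL,
                       sizes = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  bad <- setdiff(stages, ppc_stages())
  if (length(bad) > 0) {
    stop("invalid stage id(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(ppc_stages(), collapse = ", "))
  }
  features <- match.arg(features, several.ok = TRUE)
  if (!selection$method %in% c("pearson", "rf_importance", "relief")) {
    stop("unknown selection method ", selection$method)
  }
  if (inherits(model, "ppc_model_config")) model <- list(model)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 layout = layout, canopy = canopy, features = features,
                 glcm = glcm, red_edge = red_edge, buffer_m = buffer_m,
                 selection = selection, model = model,
                 split_ratio = split_ratio, stratify_by = stratify_by,
                 sizes = sizes),
            class = "run_config")
}

config_digest <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg <- rapply(unclass(config), function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Simulate and write all scenes of a run
#'
#' One directory per growth stage under `<out_dir>/scenes/`, each holding the
#' reflectance and RGB rasters, ROI polygons and truth CSV.
#'
#' @param config A [run_config()].
#' @param force Overwrite an existing non-empty scene directory.
#' @return Tibble manifest of written files.
#' @export
run_simulate <- function(config, force = FALSE) {
  scene_dir <- file.path(config$out_dir, "scenes")
  if (dir.exists(scene_dir) && length(list.files(scene_dir)) > 0 && !force) {
    stop("output directory ", scene_dir,
         " is not empty; use force = TRUE to overwrite")
  }
  manifests <- purrr::map(config$stages, function(st) {
    truth <- simulate_ppc_truth(config$layout, config$canopy, st, config$seed)
    bundle <- simulate_scene(config$layout, truth, config$canopy, config$seed)
    write_scene(bundle, file.path(scene_dir, st)) |>
      mutate(stage = st)
  })
  purrr::list_rbind(manifests)
}

#' Extract the sample table of a run from files
#'
#' Reads each stage's scene from disk, inward-buffers the plot ROIs by
#' `buffer_m`, rasterizes them to masks, extracts the configured feature
#' families, and writes `samples.csv` plus its provenance sidecar.
#'
#' @param config A [run_config()].
#' @return The sample table (invisibly written to
#'   `<out_dir>/samples.csv`).
#' @export
run_extract <- function(config) {
  tabs <- purrr::map(config$stages, function(st) {
    dir <- file.path(config$out_dir, "scenes", st)
    if (!dir.exists(dir)) stop("missing scene directory ", dir)
    bundle <- read_scene(dir)
    rois <- read_plot_rois(file.path(dir, "plots.geojson"))
    masks <- purrr::map(
      setNames(rois, purrr::map_chr(rois, "plot_id")),
      function(r) {
        rasterize_roi(buffer_inward(r, config$buffer_m),
                      bundle$geotransform, dim(bundle$reflectance)[1:2])
      })
    extract_features(bundle, features = config$features, spec = config$glcm,
                     red_edge = config$red_edge, masks = masks)
  })
  out <- purrr::list_rbind(tabs)
  attr(out, "provenance") <- attr(tabs[[1]], "provenance")
  write_sample_table(out, file.path(config$out_dir, "samples.csv"))
  invisible(out)
}

run_selection <- function(data, config) {
  sel <- config$selection
  switch(sel$method,
    pearson = pearson_screen(data, threshold = sel$threshold %||% 0.5,
                             top_k = sel$top_k),
    rf_importance = rf_importance_rank(data, top_k = sel$top_k %||% 10,
                                       seed = config$seed),
    relief = relief_weights(data, top_k = sel$top_k %||% 10,
                            k_neighbors = sel$k_neighbors %||% 10,
                            seed = config$seed))
}

#' Select features, fit models and evaluate a run
#'
#' Splits the sample table, runs the configured selection on the training
#' rows, and fits every configured model family to each feature subset (the
#' retained set by default, or each size of the `sizes` sweep), writing the
#' evaluation report and a JSON manifest.
#'
#' @param config A [run_config()].
#' @param data Optional in-memory sample table (read from
#'   `<out_dir>/samples.csv` when omitted).
#' @return List with `selection` (a `ppc_selection`), `report` (tibble of
#'   per-model metrics) and `models` (fitted `ppc_model`s of the full
#'   retained set).
#' @export
run_model <- function(config, data = NULL) {
  data <- data %||% read_sample_table(file.path(config$out_dir, "samples.csv"))
  data <- split_samples(data, ratio = config$split_ratio, seed = config$seed,
                        stratify_by = config$stratify_by)
  selection <- run_selection(data, config)
  subsets <- if (is.null(config$sizes)) {
    list(retained = selection$feature[selection$retained])
  } else {
    subset_sweep(selection, config$sizes)
  }
  report <- purrr::imap(subsets, function(feats, subset_name) {
    purrr::map(config$model, function(cfg) {
      m <- fit_ppc_model(data, feats, cfg, seed = config$seed)
      glance(m) |>
        mutate(family = cfg$family, subset = subset_name,
               n_features = length(feats),
               method = selection$method[1], .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  models <- purrr::map(
    setNames(config$model, purrr::map_chr(config$model, "family")),
    ~ fit_ppc_model(data, subsets[[1]], .x, seed = config$seed))
  if (dir.exists(config$out_dir)) {
    readr::write_csv(report, file.path(config$out_dir, "eval_report.csv"))
    readr::write_csv(tidy(selection),
                     file.path(config$out_dir, "selection.csv"))
  }
  list(selection = selection, report = report, models = models)
}

#' Run the full pipeline
#'
#' simulate -> extract -> model, writing a run manifest
#' (`manifest.json`) with the configuration digest, package version,
#' per-file MD5 digests and timing.
#'
#' @param config A [run_config()].
#' @param force Passed to [run_simulate()].
#' @return The [run_model()] result, with the manifest in attribute
#'   `"manifest"`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  t0 <- Sys.time()
  sim_manifest <- run_simulate(config, force = force)
  samples <- run_extract(config)
  result <- run_model(config, samples)
  files <- c(file.path(config$out_dir, "samples.csv"),
             file.path(config$out_dir, "eval_report.csv"),
             file.path(config$out_dir, "selection.csv"))
  manifest <- list(
    config_digest = config_digest(config),
    package_version = as.character(utils::packageVersion("uavppc")),
    seed = config$seed,
    scene_files = purrr::map2(sim_manifest$file, sim_manifest$md5,
                              ~ list(file = .x, md5 = unname(.y))),
    output_digests = as.list(tools::md5sum(files[file.exists(files)])),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(result, "manifest") <- manifest
  result
}
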