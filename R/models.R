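#' Split samples into training and validation partitions
#'
#' Seeded random split at a given training fraction (default 3:1, i.e. 0.75),
#' adding a `.split` column with values `"train"`/`"validation"`. The
#' training size is `floor(ratio * n)` overall, or per stratum when
#' `stratify_by` is given.
#'
#' @param data Sample table.
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed.
#' @param stratify_by Optional column name (e.g. `"stage"` or
#'   `"treatment"`) to balance across partitions.
#' @return The input tibble with a `.split` column.
#' @export
split_samples <- function(data, ratio = 0.75, seed = 1L, stratify_by = NULL) {
  n <- nrow(data)
  if (n < 8) stop("need at least 8 samples to split")
  stopifnot(ratio > 0, ratio < 1)
  data <- as_tibble(data)
  assign_split <- function(idx, seed_offset) {
    k <- length(idx)
    n_train <- floor(ratio * k)
    if (n_train < 1 || n_train >= k) {
      stop("partition would be empty (stratum of size ", k, ")")
    }
    withr::with_seed(substream_seed(seed, paste0("split-", seed_offset)), {
      tr <- sample(idx, n_train)
    })
    tr
  }
  split <- rep("validation", n)
  if (is.null(stratify_by)) {
    split[assign_split(seq_len(n), "all")] <- "train"
  } else {
    if (!stratify_by %in% names(data)) stop("unknown stratum column ", stratify_by)
    for (lev in unique(data[[stratify_by]])) {
      idx <- which(data[[stratify_by]] == lev)
      if (length(idx) < 2) stop("stratum \"", lev, "\" has fewer than 2 samples")
      split[assign_split(idx, lev)] <- "train"
    }
  }
  data$.split <- split
  data
}

#' Standardize features with training statistics only
#'
#' Z-scores every feature using the mean and standard deviation of the
#' training rows; the same transform is applied to validation rows, so no
#' validation information leaks into the scaler. Zero-variance training
#' features are dropped with a warning.
#'
#' @param data Sample table with a `.split` column (all rows are treated as
#'   training when absent).
#' @param features Feature columns to scale (default [feature_columns()]).
#' @param response Response column name.
#' @return List with `data` (scaled tibble) and `scaler` (tibble `feature`,
#'   `mean`, `sd`).
#' @export
standardize_features <- function(data, features = NULL,
                                 response = "ppc_g_per_kg") {
  features <- features %||% feature_columns(data, response)
  tr <- train_idx(data)
  mu <- purrr::map_dbl(features, ~ mean(data[[.x]][tr]))
  sg <- purrr::map_dbl(features, ~ sd(data[[.x]][tr]))
  drop <- features[is.na(sg) | sg == 0]
  if (length(drop) > 0) {
    warning(length(drop), " zero-variance feature(s) dropped: ",
            paste(head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ..." else "")
    keep <- !(features %in% drop)
    features <- features[keep]; mu <- mu[keep]; sg <- sg[keep]
  }
  for (k in seq_along(features)) {
    data[[features[k]]] <- (data[[features[k]]] - mu[k]) / sg[k]
  }
  list(data = data, scaler = tibble(feature = features, mean = mu, sd = sg))
}

apply_scaler <- function(X, scaler) {
  X <- X[, scaler$feature, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Model configuration for PPC regression
#'
#' Hyperparameters of the three regression families: a random forest with
#' 100 trees, minimum leaf size 5 and at most 20 splits per tree (`mtry`
#' defaults to `max(1, floor(p/3))`); an RBF-kernel epsilon-insensitive
#' support vector machine with `C = 10` and `gamma = 0.1`; and
#' `K = 7`-nearest-neighbour regression on z-scored inputs.
#'
#' @param family `"rf"`, `"svm"` or `"knn"`.
#' @param ntrees,min_leaf,max_splits,mtry Random-forest settings.
#' @param cost,gamma,epsilon SVM settings.
#' @param k KNN neighbour count.
#' @param cv_folds Folds for [tune_cv()].
#' @param scale Standardize features before fitting (default `TRUE`).
#' @return A `ppc_model_config` object.
#' @export
ppc_model_config <- function(family = c("svm", "rf", "knn"), ntrees = 100,
                             min_leaf = 5, max_splits = 20, mtry = NULL,
                             cost = 10, gamma = 0.1, epsilon = 0.1, k = 7,
                             cv_folds = 5, scale = TRUE) {
  family <- match.arg(family)
  stopifnot(ntrees >= 1, min_leaf >= 1, max_splits >= 1, cost > 0, gamma > 0,
            epsilon >= 0, k >= 1, cv_folds >= 2)
  structure(list(family = family, ntrees = ntrees, min_leaf = min_leaf,
                 max_splits = max_splits, mtry = mtry, cost = cost,
                 gamma = gamma, epsilon = epsilon, k = k, cv_folds = cv_folds,
                 scale = scale),
            class = "ppc_model_config")
}

fit_engine <- function(X, y, config, seed) {
  if (sd(y) == 0) {
    # degenerate target: every family reduces to the constant predictor
    return(structure(list(value = y[1]), class = "uavppc_constant"))
  }
  switch(config$family,
    rf = withr::with_seed(substream_seed(seed, "rf-fit"), {
      randomForest::randomForest(
        x = X, y = y, ntree = config$ntrees,
        mtry = config$mtry %||% max(1L, floor(ncol(X) / 3)),
        nodesize = config$min_leaf, maxnodes = config$max_splits + 1L)
    }),
    svm = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = config$cost,
                     gamma = config$gamma, epsilon = config$epsilon,
                     scale = FALSE),
    knn = caret::knnreg(x = as.data.frame(X), y = y, k = config$k),
    stop("unknown model family ", config$family)
  )
}

predict_engine <- function(fit, config, X) {
  if (inherits(fit, "uavppc_constant")) {
    rep(fit$value, nrow(X))
  } else if (config$family == "knn") {
    as.numeric(predict(fit, as.data.frame(X)))
  } else {
    as.numeric(predict(fit, X))
  }
}

#' Cross-validated hyperparameter selection
#'
#' Seeded `cv_folds`-fold cross-validation on the training rows; returns the
#' configuration of the grid row minimizing mean CV RMSE. An empty or `NULL`
#' grid returns the configuration unchanged.
#'
#' @param data Sample table with a `.split` column.
#' @param config A [ppc_model_config()].
#' @param grid Data frame of configuration overrides (columns named after
#'   `ppc_model_config` fields, e.g. `cost`, `gamma`, `k`).
#' @param features Feature columns (default [feature_columns()]).
#' @param response Response column.
#' @param seed Integer seed (fold assignment).
#' @return The winning `ppc_model_config`, with the CV table in attribute
#'   `"cv_results"`.
#' @export
tune_cv <- function(data, config, grid = NULL, features = NULL,
                    response = "ppc_g_per_kg", seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) return(config)
  features <- features %||% feature_columns(data, response)
  tr <- train_idx(data)
  n <- length(tr)
  folds <- withr::with_seed(substream_seed(seed, "cv-folds"), {
    sample(rep(seq_len(config$cv_folds), length.out = n))
  })
  if (min(table(folds)) < 2) stop("cross-validation folds smaller than 2")
  Xall <- as.matrix(data[tr, features, drop = FALSE])
  yall <- data[[response]][tr]
  rmse_of <- function(cfg) {
    errs <- purrr::map_dbl(seq_len(config$cv_folds), function(f) {
      inb <- folds != f
      mu <- colMeans(Xall[inb, , drop = FALSE])
      sg <- apply(Xall[inb, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xall[inb, , drop = FALSE], 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xall[!inb, , drop = FALSE], 2, mu), 2, sg, "/")
      tryCatch(suppressWarnings({
        fit <- fit_engine(if (cfg$scale) Xtr else Xall[inb, , drop = FALSE],
                          yall[inb], cfg, seed)
        pred <- predict_engine(fit, cfg,
                               if (cfg$scale) Xte
                               else Xall[!inb, , drop = FALSE])
        sqrt(mean((yall[!inb] - pred)^2))
      # infeasible grid points (e.g. more neighbours than fold samples)
      # simply lose the comparison
      }), error = function(e) Inf)
    })
    mean(errs)
  }
  cvr <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    cfg <- config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    rmse_of(cfg)
  })
  best <- which.min(cvr)
  out <- config
  for (nm in names(grid)) out[[nm]] <- grid[[nm]][best]
  attr(out, "cv_results") <- bind_cols(as_tibble(grid), tibble(rmse = cvr))
  out
}

#' Fit a PPC regression model
#'
#' Standardizes the selected features with training statistics (unless
#' disabled), fits the configured family on the training rows only, and
#' stores predictions for both partitions.
#'
#' @param data Sample table with a `.split` column (all rows train when
#'   absent).
#' @param features Character vector of feature columns (e.g. from
#'   [subset_sweep()]).
#' @param config A [ppc_model_config()].
#' @param response Response column.
#' @param seed Integer seed (random-forest bootstrap).
#' @return A `ppc_model` object.
#' @export
fit_ppc_model <- function(data, features = NULL, config = ppc_model_config(),
                          response = "ppc_g_per_kg", seed = 1L) {
  features <- features %||% feature_columns(data, response)
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    stop("features not in data: ", paste(missing_cols, collapse = ", "))
  }
  tr <- train_idx(data)
  Xall <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(Xall)) stop("missing feature values; clean features before fitting")
  scaler <- NULL
  if (config$scale) {
    mu <- colMeans(Xall[tr, , drop = FALSE])
    sg <- apply(Xall[tr, , drop = FALSE], 2, sd)
    if (any(sg == 0)) {
      keep <- sg > 0
      warning(sum(!keep), " zero-variance feature(s) dropped before fitting")
      features <- features[keep]
      Xall <- Xall[, keep, drop = FALSE]; mu <- mu[keep]; sg <- sg[keep]
    }
    scaler <- tibble(feature = features, mean = mu, sd = sg)
    Xall <- sweep(sweep(Xall, 2, mu), 2, sg, "/")
  }
  y <- data[[response]]
  fit <- fit_engine(Xall[tr, , drop = FALSE], y[tr], config, seed)
  pred <- predict_engine(fit, config, Xall)
  split <- if (".split" %in% names(data)) data$.split else rep("train", nrow(data))
  preds <- tibble(.split = split, observed = y, predicted = pred)
  if ("plot_id" %in% names(data)) preds$plot_id <- data$plot_id
  if ("stage" %in% names(data)) preds$stage <- data$stage
  structure(list(fit = fit, config = config, features = features,
                 scaler = scaler, response = response, seed = seed,
                 predictions = preds),
            class = "ppc_model")
}

#' @export
print.ppc_model <- function(x, ...) {
  g <- glance(x)
  cat("<ppc_model> family=", x$config$family, ", ", length(x$features),
      " features\n", sep = "")
  print(g)
  invisible(x)
}

#' Predict PPC for new samples
#'
#' @param object A `ppc_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric predictions (NA where any feature is missing).
#' @export
predict.ppc_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  ok <- rowSums(is.na(X)) == 0
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    Xo <- X[ok, , drop = FALSE]
    if (!is.null(object$scaler)) Xo <- apply_scaler(Xo, object$scaler)
    out[ok] <- predict_engine(object$fit, object$config, Xo)
  }
  out
}

#' Regression evaluation metrics
#'
#' Computes `R2 = 1 - SSE/SST`, `RMSE = sqrt(mean((obs - pred)^2))`, `SD`
#' (the sample standard deviation of the observed values) and the relative
#' prediction deviation `RPD = SD / RMSE`. A perfect fit gives `RPD = Inf`;
#' a constant observed vector gives `R2 = NA`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return One-row tibble: `n`, `r2`, `rmse`, `sd`, `rpd`.
#' @export
evaluate <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  rmse <- sqrt(sse / length(observed))
  sdy <- sd(observed)
  tibble(n = length(observed),
         r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         rmse = rmse,
         sd = sdy,
         rpd = if (rmse > 0) sdy / rmse else Inf)
}

#' Calibration/validation metrics of a fitted model
#'
#' @param x A `ppc_model`.
#' @param ... Unused.
#' @return Tibble with one row per partition (`calibration`, `validation`)
#'   and columns `n`, `r2`, `rmse`, `sd`, `rpd`.
#' @method glance ppc_model
#' @export
glance.ppc_model <- function(x, ...) {
  x$predictions |>
    mutate(partition = ifelse(.data$.split == "train", "calibration",
                              "validation")) |>
    group_by(.data$partition) |>
    dplyr::group_modify(~ evaluate(.x$observed, .x$predicted)) |>
    ungroup()
}

#' @method tidy ppc_model
#' @export
tidy.ppc_model <- function(x, ...) {
  x$predictions |>
    mutate(partition = ifelse(.data$.split == "train", "calibration",
                              "validation")) |>
    select(-".split")
}

#' Observed-versus-predicted scatter of a fitted model
#'
#' @param object A `ppc_model`.
#' @param ... Unused.
#' @return A ggplot object with a 1:1 reference line.
#' @method autoplot ppc_model
#' @export
autoplot.ppc_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "observed PPC (g/kg)", y = "predicted PPC (g/kg)") +
    ggplot2::theme_minimal()
}
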