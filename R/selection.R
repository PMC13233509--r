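ppc_key_cols <- function() {
  c("plot_id", "treatment", "p_rate", "stage", ".split")
}

train_idx <- function(data) {
  if (".split" %in% names(data)) which(data$.split == "train")
  else seq_len(nrow(data))
}

#' Identify feature columns of a sample table
#'
#' Feature columns are the provenance-tagged columns when the table carries a
#' provenance attribute (see [extract_features()]), otherwise all numeric
#' columns except the key columns and the response.
#'
#' @param data Sample table.
#' @param response Response column name.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(data, response = "ppc_g_per_kg") {
  prov <- attr(data, "provenance")
  if (!is.null(prov)) {
    intersect(prov$feature, names(data))
  } else {
    num <- names(data)[purrr::map_lgl(data, is.numeric)]
    setdiff(num, c(ppc_key_cols(), response))
  }
}

# Training-rows design matrix with feature hygiene: features containing
# missing values or with zero variance on the training rows are dropped and
# recorded, matching the selection/standardization contract.
selection_matrix <- function(data, response, features = NULL) {
  feats <- features %||% feature_columns(data, response)
  if (length(feats) == 0) stop("no feature columns found")
  tr <- train_idx(data)
  if (length(tr) < 3) stop("need at least 3 training samples")
  X <- as.matrix(data[tr, feats, drop = FALSE])
  y <- data[[response]][tr]
  if (anyNA(y)) stop("missing values in the response on training rows")
  bad_na <- feats[colSums(is.na(X)) > 0]
  sds <- apply(X, 2, sd)
  bad_const <- feats[!is.na(sds) & sds == 0]
  dropped <- union(bad_na, bad_const)
  keep <- setdiff(feats, dropped)
  if (length(dropped) > 0) {
    warning(length(dropped), " feature(s) dropped before selection ",
            "(missing values or zero variance on training rows)")
  }
  if (length(keep) == 0) stop("all features constant or missing on training rows")
  list(X = X[, keep, drop = FALSE], y = y, features = keep, dropped = dropped)
}

new_ppc_selection <- function(feature, score, method, retained, dropped,
                              response) {
  ord <- order(-abs(score), feature)
  out <- tibble(feature = feature[ord], score = score[ord],
                rank = seq_along(feature), method = method,
                retained = retained[ord])
  attr(out, "dropped") <- dropped
  attr(out, "response") <- response
  class(out) <- c("ppc_selection", class(out))
  out
}

#' Pearson correlation screening
#'
#' Scores every feature by its Pearson correlation with the response on the
#' training rows and retains features with `|r| >= threshold` (or the
#' `top_k` by `|r|` when given). Ranking is by `|r|` descending with ties
#' broken by feature name.
#'
#' @param data Sample table (rows tagged `.split == "train"` are used when a
#'   split column is present).
#' @param response Response column (default `ppc_g_per_kg`).
#' @param threshold Absolute-correlation retention cutoff (default 0.5).
#' @param top_k Retain the top `k` by `|r|` instead of thresholding.
#' @param features Optional explicit feature set.
#' @return A `ppc_selection` tibble: `feature`, `score`, `rank`, `method`,
#'   `retained`, with dropped-feature names in the `"dropped"` attribute.
#' @export
pearson_screen <- function(data, response = "ppc_g_per_kg", threshold = 0.5,
                           top_k = NULL, features = NULL) {
  sm <- selection_matrix(data, response, features)
  score <- as.numeric(cor(sm$X, sm$y))
  retained <- if (!is.null(top_k)) {
    rank(-abs(score), ties.method = "first") <= top_k
  } else abs(score) >= threshold
  new_ppc_selection(sm$features, score, "pearson", retained, sm$dropped,
                    response)
}

#' Random-forest importance ranking
#'
#' Ranks features by the impurity-reduction (node-purity) importance of a
#' seeded regression forest grown on the training rows, and retains the
#' `top_k` (default 10) most important features.
#'
#' @inheritParams pearson_screen
#' @param top_k Number of features to retain (clipped to the feature count
#'   with a warning).
#' @param ntrees,min_leaf,max_splits Forest size and tree complexity
#'   (defaults 100 trees, minimum leaf size 5, at most 20 splits per tree).
#' @param mtry Predictors sampled per split; default `max(1, floor(p/3))`.
#' @param seed Integer seed controlling bootstrap and feature subsampling.
#' @return A `ppc_selection` tibble (see [pearson_screen()]).
#' @export
rf_importance_rank <- function(data, response = "ppc_g_per_kg", top_k = 10,
                               ntrees = 100, min_leaf = 5, max_splits = 20,
                               mtry = NULL, seed = 1L, features = NULL) {
  sm <- selection_matrix(data, response, features)
  p <- ncol(sm$X)
  if (top_k > p) {
    warning("top_k = ", top_k, " exceeds the ", p,
            " available features; clipped")
    top_k <- p
  }
  mtry <- mtry %||% max(1L, floor(p / 3))
  fit <- withr::with_seed(substream_seed(seed, "rf-importance"), {
    randomForest::randomForest(x = sm$X, y = sm$y, ntree = ntrees,
                               mtry = mtry, nodesize = min_leaf,
                               maxnodes = max_splits + 1L)
  })
  score <- as.numeric(fit$importance[, "IncNodePurity"])
  retained <- rank(-score, ties.method = "first") <= top_k
  new_ppc_selection(sm$features, score, "rf_importance", retained,
                    sm$dropped, response)
}

#' RReliefF feature weighting
#'
#' Regression Relief: for each sampled training instance, the `k_neighbors`
#' nearest training neighbours (Manhattan distance on features scaled to
#' `[0, 1]`) contribute, with exponentially rank-decayed influence, to the
#' accumulated probabilities of a feature difference, of a response
#' difference, and of their co-occurrence; the final weight of a feature is
#' the difference between its conditional contribution among
#' response-different and response-alike neighbour pairs. Constant features
#' receive weight 0. Ranking is by weight descending; the `top_k` features
#' are retained.
#'
#' @inheritParams rf_importance_rank
#' @param k_neighbors Nearest neighbours per instance (default 10).
#' @param n_iterations Instances sampled (default: all training rows, taken
#'   in order — fully deterministic; when fewer, a seeded sample is drawn).
#' @param sigma Rank-decay scale of neighbour influence.
#' @return A `ppc_selection` tibble (see [pearson_screen()]).
#' @export
relief_weights <- function(data, response = "ppc_g_per_kg", top_k = 10,
                           k_neighbors = 10, n_iterations = NULL, sigma = 10,
                           seed = 1L, features = NULL) {
  sm <- selection_matrix(data, response, features)
  n <- nrow(sm$X); p <- ncol(sm$X)
  if (n < k_neighbors + 1) {
    stop("RReliefF needs at least k_neighbors + 1 = ", k_neighbors + 1,
         " training samples, got ", n)
  }
  if (top_k > p) {
    warning("top_k = ", top_k, " exceeds the ", p,
            " available features; clipped")
    top_k <- p
  }
  # scale features to [0, 1]
  rng <- apply(sm$X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(sm$X, 2, rng[1, ]), 2, span, "/")
  ry <- diff(range(sm$y))
  idx <- if (is.null(n_iterations) || n_iterations >= n) {
    seq_len(n)
  } else {
    withr::with_seed(substream_seed(seed, "relief"),
                     sample.int(n, n_iterations))
  }
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  w_rank <- exp(-((seq_len(k_neighbors)) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)
  ndc <- 0; ndf <- numeric(p); ndcdf <- numeric(p); m_total <- 0
  if (ry > 0) {
    for (i in idx) {
      ord <- order(D[i, ], seq_len(n))
      nb <- setdiff(ord, i)[seq_len(k_neighbors)]
      dy <- abs(sm$y[nb] - sm$y[i]) / ry
      df <- abs(Xs[nb, , drop = FALSE] -
                  matrix(Xs[i, ], k_neighbors, p, byrow = TRUE))
      ndc <- ndc + sum(dy * w_rank)
      ndf <- ndf + colSums(df * w_rank)
      ndcdf <- ndcdf + colSums(df * (dy * w_rank))
      m_total <- m_total + 1
    }
  }
  score <- if (ndc > 0 && (m_total - ndc) > 0) {
    ndcdf / ndc - (ndf - ndcdf) / (m_total - ndc)
  } else numeric(p)
  retained <- rank(-score, ties.method = "first") <= top_k
  new_ppc_selection(sm$features, score, "relief", retained, sm$dropped,
                    response)
}

#' Nested feature subsets from a ranking
#'
#' Prefixes of the ranked feature list, one per requested size; smaller
#' subsets are nested in larger ones.
#'
#' @param selection A `ppc_selection`.
#' @param sizes Positive subset sizes, each at most the number of ranked
#'   features.
#' @return Named list (`top<k>`) of character vectors of feature names.
#' @export
subset_sweep <- function(selection, sizes) {
  stopifnot(inherits(selection, "ppc_selection"))
  if (any(sizes <= 0)) stop("subset sizes must be positive")
  if (any(sizes > nrow(selection))) {
    stop("subset size exceeds the ", nrow(selection), " ranked features")
  }
  setNames(purrr::map(sizes, ~ selection$feature[seq_len(.x)]),
           paste0("top", sizes))
}

#' @method tidy ppc_selection
#' @export
tidy.ppc_selection <- function(x, ...) {
  as_tibble(unclass(x)[c("feature", "score", "rank", "method", "retained")])
}

#' Bar chart of a feature ranking
#'
#' @param object A `ppc_selection`.
#' @param top_n Number of top-ranked features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppc_selection
#' @export
autoplot.ppc_selection <- function(object, top_n = 20, ...) {
  df <- head(as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$feature,
                                                      abs(.data$score)))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$retained)) +
    ggplot2::labs(x = paste0("score (", df$method[1], ")"), y = NULL) +
    ggplot2::theme_minimal()
}
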