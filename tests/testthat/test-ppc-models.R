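planted_split <- function(seed = 1, n = 75) {
  split_samples(make_planted_features(n = n, seed = seed), seed = seed)
}

test_that("3:1 splitting follows the floor rule and the seeding contract", {
  d8 <- tibble::tibble(ppc_g_per_kg = 1:8, x = 1:8)
  s8 <- split_samples(d8, seed = 1)
  expect_equal(sum(s8$.split == "train"), 6L)
  expect_equal(sum(s8$.split == "validation"), 2L)

  d75 <- make_planted_features(n = 75, seed = 1)
  s75 <- split_samples(d75, seed = 1)
  expect_equal(sum(s75$.split == "train"), 56L)  # floor(0.75*75)
  expect_equal(sum(s75$.split == "validation"), 19L)

  expect_identical(s75$.split, split_samples(d75, seed = 1)$.split)
  expect_false(identical(s75$.split, split_samples(d75, seed = 2)$.split))

  # stratified split balances the stratum across partitions
  ds <- tibble::tibble(ppc_g_per_kg = 1:40, x = 1:40,
                       stage = rep(c("T1", "T2"), each = 20))
  ss <- split_samples(ds, seed = 3, stratify_by = "stage")
  tab <- table(ss$stage, ss$.split)
  expect_equal(unname(tab[, "train"]), c(15L, 15L))
  d1 <- tibble::tibble(ppc_g_per_kg = 1:9, x = 1:9,
                       stage = c(rep("T1", 8), "T2"))
  expect_error(split_samples(d1, seed = 1, stratify_by = "stage"),
               "fewer than 2")
})

test_that("standardization uses training statistics only", {
  df <- planted_split(seed = 4)
  out <- standardize_features(df)
  tr <- out$data$.split == "train"
  expect_equal(mean(out$data$info1[tr]), 0, tolerance = 1e-12)
  expect_equal(sd(out$data$info1[tr]), 1, tolerance = 1e-12)

  # a validation row equal to a training row scales identically
  df2 <- df
  i_tr <- which(df2$.split == "train")[1]
  i_va <- which(df2$.split == "validation")[1]
  df2[i_va, setdiff(names(df2), ".split")] <-
    df2[i_tr, setdiff(names(df2), ".split")]
  out2 <- standardize_features(df2)
  expect_equal(as.numeric(out2$data[i_va, c("info1", "noise01")]),
               as.numeric(out2$data[i_tr, c("info1", "noise01")]))

  # perturbing validation rows does not change the scaler
  df3 <- df
  df3$info1[df3$.split == "validation"] <- 99
  expect_identical(standardize_features(df3)$scaler, out$scaler)
})

test_that("cross-validated tuning picks sensible grid points", {
  df <- planted_split(seed = 6)
  cfg <- ppc_model_config("svm")
  expect_identical(tune_cv(df, cfg, grid = NULL), cfg)

  g1 <- data.frame(cost = 10, gamma = 0.1)
  t1 <- tune_cv(df, cfg, g1, seed = 1)
  expect_equal(t1$cost, 10); expect_equal(t1$gamma, 0.1)

  # degenerate K = n loses to K = 7 on structured data
  kcfg <- ppc_model_config("knn")
  tk <- tune_cv(df, kcfg, data.frame(k = c(7, 56)), seed = 1)
  expect_equal(tk$k, 7)
  expect_s3_class(attr(tk, "cv_results"), "tbl_df")
})

test_that("fitting honours family contracts and degenerate targets", {
  df <- planted_split(seed = 2)
  # 1-NN reproduces its training targets exactly
  m1 <- fit_ppc_model(df, c("info1", "info2", "info3"),
                      ppc_model_config("knn", k = 1), seed = 1)
  tr <- m1$predictions$.split == "train"
  expect_equal(m1$predictions$predicted[tr], m1$predictions$observed[tr])

  # constant target: every family predicts the constant with RMSE 0
  dfc <- df
  dfc$ppc_g_per_kg <- 3.3
  for (fam in c("rf", "svm", "knn")) {
    mc <- fit_ppc_model(dfc, c("info1", "info2"),
                        ppc_model_config(fam, epsilon = 0), seed = 1)
    g <- glance(mc)
    expect_equal(g$rmse[g$partition == "validation"], 0, tolerance = 1e-9)
  }

  cfg_bad <- ppc_model_config("rf"); cfg_bad$family <- "boost"
  expect_error(fit_ppc_model(df, "info1", cfg_bad, seed = 1), "unknown")
  expect_error(fit_ppc_model(df, "nope", ppc_model_config("rf")), "nope")

  # planted linear signal, low noise: SVM generalizes strongly
  msvm <- fit_ppc_model(df, c("info1", "info2", "info3"),
                        ppc_model_config("svm"), seed = 1)
  g <- glance(msvm)
  expect_gt(g$r2[g$partition == "validation"], 0.9)

  # RF is reproducible bit-for-bit under a fixed seed
  mrf1 <- fit_ppc_model(df, c("info1", "info2"), ppc_model_config("rf"), seed = 9)
  mrf2 <- fit_ppc_model(df, c("info1", "info2"), ppc_model_config("rf"), seed = 9)
  expect_identical(mrf1$predictions, mrf2$predictions)
})

test_that("evaluation matches the independent oracle and its identities", {
  ev <- evaluate(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(ev$rmse, 0.1581139, tolerance = 1e-6)
  expect_equal(ev$r2, 0.98)
  expect_equal(ev$sd, 1.290994, tolerance = 1e-6)
  expect_equal(ev$rpd, 8.164966, tolerance = 1e-6)

  expect_equal(evaluate(1:5, 1:5)$r2, 1)
  expect_equal(evaluate(1:5, 1:5)$rmse, 0)
  expect_true(is.infinite(evaluate(1:5, 1:5)$rpd))
  expect_equal(evaluate(c(1, 2, 3), rep(2, 3))$r2, 0)
  expect_true(is.na(evaluate(rep(2, 4), c(1, 2, 3, 4))$r2))

  withr::with_seed(12, {
    for (i in 1:20) {
      obs <- rnorm(10); pred <- obs + rnorm(10, 0, 0.3)
      ev <- evaluate(obs, pred)
      want <- oracle_evaluate(obs, pred)
      expect_equal(c(ev$r2, ev$rmse, ev$sd, ev$rpd), unname(want),
                   tolerance = 1e-10)
      expect_equal(ev$rpd * ev$rmse, ev$sd, tolerance = 1e-12)
    }
  })
})

test_that("inversion maps are consistent with tabular predictions", {
  m <- noiseless_model()
  lay <- small_layout()
  bundles <- simulate_experiment(lay, m, seed = 3)
  samples <- extract_experiment(bundles, features = c("ci", "vi", "fvc", "tf"))
  samples <- split_samples(samples, seed = 3)
  feats <- c("NDVI", "840-Mea", "R840")
  fit <- fit_ppc_model(samples, feats, ppc_model_config("svm"), seed = 3)

  sc <- bundles[["T1"]]
  map <- inversion_map(fit, sc)

  # border texture pixels propagate missing
  expect_true(all(is.na(map[1, ])))
  expect_false(anyNA(map[3:10, 3:10]))

  # plot-mean of the map ranks plots exactly as ground truth (noise-free)
  truth <- sc$truth
  plot_means <- vapply(truth$plot_id,
                       function(id) mean(map[sc$plot_masks[[id]]], na.rm = TRUE),
                       numeric(1))
  expect_equal(cor(plot_means, truth$ppc_g_per_kg, method = "spearman"), 1)

  # constant feature rasters reproduce the tabular prediction
  sc2 <- sc
  v <- c(0.05, 0.1, 0.08, 0.3, 0.4, 0.45)
  for (b in 1:6) sc2$reflectance[, , b] <- v[b]
  map2 <- suppressWarnings(inversion_map(fit, sc2))
  fr <- suppressWarnings(feature_rasters(sc2, feats))
  row <- tibble::as_tibble(purrr::map(fr, ~ .x[5, 5]))
  expect_equal(row$NDVI, (0.45 - 0.08) / (0.45 + 0.08))
  expect_equal(unique(round(as.numeric(map2[3:8, 3:8]), 9)),
               round(predict(fit, row), 9))

  # plot-aggregate-only features are refused by name
  fitf <- fit_ppc_model(samples, c("FVC", "NDVI"), ppc_model_config("svm"),
                        seed = 3)
  expect_error(inversion_map(fitf, sc), "FVC")
})

test_that("no validation information leaks into selection, scaler or fit", {
  lay <- small_layout()
  bundles <- simulate_experiment(lay, canopy_model(), seed = 5)
  samples <- extract_experiment(bundles, features = c("ci", "vi", "fvc", "tf"))
  samples <- split_samples(samples, seed = 5)

  run_once <- function(d) {
    sel <- rf_importance_rank(d, seed = 5)
    fit <- fit_ppc_model(d, sel$feature[sel$retained],
                         ppc_model_config("svm"), seed = 5)
    tr <- fit$predictions$.split == "train"
    list(scores = tidy(sel), scaler = fit$scaler,
         train_pred = fit$predictions$predicted[tr])
  }
  base <- run_once(samples)
  pert <- samples
  val <- pert$.split == "validation"
  pert$ppc_g_per_kg[val] <- pert$ppc_g_per_kg[val] * 3 + 1
  after <- run_once(pert)
  expect_identical(base$scores, after$scores)
  expect_identical(base$scaler, after$scaler)
  expect_identical(base$train_pred, after$train_pred)
})
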