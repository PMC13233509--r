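test_that("pearson screening matches the closed form and tie rules", {
  y <- c(1, 3, 2, 4)
  df <- tibble::tibble(ppc_g_per_kg = y, a_lin = 2 * y + 1, b_neg = -y,
                       x = c(1, 2, 3, 4))
  sel <- pearson_screen(df)
  expect_equal(sel$score[sel$feature == "a_lin"], 1)
  expect_equal(sel$score[sel$feature == "b_neg"], -1)
  # |r| tie between a_lin and b_neg broken by name order
  expect_equal(sel$feature[1:2], c("a_lin", "b_neg"))
  # hand-computed r for x vs y
  expect_equal(sel$score[sel$feature == "x"], 0.8, tolerance = 1e-12)
  expect_equal(sel$score[sel$feature == "x"],
               oracle_pearson(df$x, y), tolerance = 1e-12)

  cdf <- tibble::tibble(ppc_g_per_kg = y, c1 = rep(1, 4), c2 = rep(2, 4))
  expect_error(suppressWarnings(pearson_screen(cdf)), "constant")
})

test_that("rf importance ranks a planted signal first and clips top_k", {
  withr::with_seed(10, {
    a <- runif(60)
    noise <- matrix(runif(60 * 20), 60)
    colnames(noise) <- sprintf("n%02d", 1:20)
    df <- tibble::tibble(ppc_g_per_kg = a + rnorm(60, 0, 0.02), A = a,
                         !!!tibble::as_tibble(noise))
  })
  sel <- rf_importance_rank(df, seed = 1)
  expect_equal(sel$feature[1], "A")
  expect_equal(sum(sel$retained), 10L)
  expect_identical(tidy(sel), tidy(rf_importance_rank(df, seed = 1)))

  # duplicated informative feature: the pair jointly dominates any noise
  df2 <- dplyr::mutate(df, A2 = A)
  sel2 <- rf_importance_rank(df2, seed = 1)
  s <- function(f) sel2$score[sel2$feature == f]
  expect_gt(s("A") + s("A2"), max(sel2$score[grepl("^n", sel2$feature)]))

  expect_warning(selc <- rf_importance_rank(df, top_k = 100, seed = 1),
                 "clipped")
  expect_equal(sum(selc$retained), 21L)
})

test_that("relief weighting separates signal, zeroes constants, nulls permutations", {
  withr::with_seed(21, {
    y <- runif(60)
    noise <- matrix(runif(60 * 10), 60)
    colnames(noise) <- sprintf("n%02d", 1:10)
    df <- tibble::tibble(ppc_g_per_kg = y, copy = y,
                         !!!tibble::as_tibble(noise))
  })
  sel <- relief_weights(df, seed = 1)
  expect_equal(sel$feature[1], "copy")
  expect_gt(sel$score[sel$feature == "copy"],
            max(sel$score[grepl("^n", sel$feature)]))

  # constant feature: zero feature-difference in every update
  dfc <- df
  dfc$flat <- 1
  attr(dfc, "provenance") <- NULL
  self <- suppressWarnings(selection_res <- relief_weights(dfc, seed = 1))
  expect_true("flat" %in% attr(selection_res, "dropped") ||
                selection_res$score[selection_res$feature == "flat"] == 0)

  # permuted target: weights hover near zero
  withr::with_seed(33, {
    y2 <- runif(200)
    noise2 <- matrix(runif(200 * 8), 200)
    colnames(noise2) <- sprintf("m%d", 1:8)
    df2 <- tibble::tibble(ppc_g_per_kg = sample(y2), !!!tibble::as_tibble(noise2))
  })
  sel2 <- relief_weights(df2, top_k = 8, seed = 1)
  expect_true(all(abs(sel2$score) < 0.1))

  expect_error(relief_weights(df[1:8, ], k_neighbors = 10), "k_neighbors")
  expect_identical(tidy(sel), tidy(relief_weights(df, seed = 1)))
})

test_that("subset sweeps are nested ranking prefixes", {
  df <- make_planted_features(seed = 5)
  sel <- pearson_screen(df, top_k = 10)
  sizes <- 10:3
  subs <- subset_sweep(sel, sizes)
  expect_length(subs, 8L)
  for (i in seq_along(sizes)) expect_length(subs[[i]], sizes[i])
  for (i in 2:length(subs)) {
    expect_true(all(subs[[i]] %in% subs[[i - 1]]))
  }
  expect_equal(subset_sweep(sel, 1)[[1]], sel$feature[1])
  expect_error(subset_sweep(sel, 0), "positive")
  expect_error(subset_sweep(sel, 10000), "exceeds")
})

test_that("selection sees only training rows", {
  df <- make_planted_features(seed = 8)
  df <- split_samples(df, seed = 8)
  base <- list(p = pearson_screen(df),
               rf = rf_importance_rank(df, seed = 2),
               rl = relief_weights(df, seed = 2))
  # perturb validation responses and features: scores must not move
  df2 <- df
  val <- df2$.split == "validation"
  df2$ppc_g_per_kg[val] <- df2$ppc_g_per_kg[val] + 100
  df2$info1[val] <- -df2$info1[val]
  after <- list(p = pearson_screen(df2),
                rf = rf_importance_rank(df2, seed = 2),
                rl = relief_weights(df2, seed = 2))
  for (k in names(base)) expect_identical(tidy(base[[k]]), tidy(after[[k]]))
})

test_that("all three selectors recover planted features (sanity sweep)", {
  hits <- purrr::map_lgl(1:8, function(s) {
    df <- make_planted_features(seed = s)
    top <- function(sel) sel$feature[1:10]
    all(c("info1", "info2", "info3") %in% top(pearson_screen(df))) &&
      all(c("info1", "info2", "info3") %in%
            top(rf_importance_rank(df, seed = s))) &&
      all(c("info1", "info2", "info3") %in% top(relief_weights(df, seed = s)))
  })
  expect_true(all(hits))
})
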