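# Independent brute-force oracles and fixture builders used across the suite.

# Brute-force GLCM statistics: enumerates every pixel pair explicitly per
# direction, builds the dense symmetric co-occurrence table, and computes the
# eight statistics from their defining sums. Kept deliberately naive and
# separate from the package implementation.
oracle_glcm_stats <- function(patch, levels = max(patch, na.rm = TRUE) + 1L,
                              directions = list(c(0, 1), c(-1, 1),
                                                c(-1, 0), c(-1, -1))) {
  per_dir <- list()
  for (d in directions) {
    P <- matrix(0, levels, levels)
    npairs <- 0
    for (r in seq_len(nrow(patch))) {
      for (c in seq_len(ncol(patch))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nrow(patch) || c2 < 1 || c2 > ncol(patch)) next
        a <- patch[r, c]; b <- patch[r2, c2]
        if (is.na(a) || is.na(b)) next
        P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
        P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
        npairs <- npairs + 2
      }
    }
    if (npairs == 0) next
    P <- P / npairs
    stopifnot(abs(sum(P) - 1) < 1e-12)
    i <- matrix(0:(levels - 1), levels, levels)
    j <- t(i)
    mea <- sum(i * P)
    v <- sum((i - mea)^2 * P)
    pe <- P[P > 0]
    per_dir[[length(per_dir) + 1]] <- c(
      Mea = mea, Var = v,
      Hom = sum(P / (1 + (i - j)^2)),
      Con = sum((i - j)^2 * P),
      Dis = sum(abs(i - j) * P),
      Ent = -sum(pe * log(pe)),
      Sem = sum(P^2),
      Cor = if (v > 1e-12) sum((i - mea) * (j - mea) * P) / v else 0)
  }
  if (length(per_dir) == 0) {
    return(setNames(rep(NA_real_, 8),
                    c("Mea", "Var", "Hom", "Con", "Dis", "Ent", "Sem", "Cor")))
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

# Independent evaluation oracle: explicit sums for R2, RMSE, sample SD and
# RPD.
oracle_evaluate <- function(obs, pred) {
  n <- length(obs)
  sse <- 0; for (i in seq_len(n)) sse <- sse + (obs[i] - pred[i])^2
  ybar <- sum(obs) / n
  sst <- 0; for (i in seq_len(n)) sst <- sst + (obs[i] - ybar)^2
  rmse <- sqrt(sse / n)
  sdy <- sqrt(sst / (n - 1))
  c(r2 = 1 - sse / sst, rmse = rmse, sd = sdy, rpd = sdy / rmse)
}

# Closed-form Pearson correlation from its defining sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Planted-signal feature table: three genuinely informative features plus
# pure-noise features, with the response a weighted sum of the informative
# ones. Coefficients keep every informative feature's population correlation
# with the response near or above 0.5, so recovery failures indicate a
# selector defect rather than a marginal draw.
make_planted_features <- function(n = 75, n_noise = 30, seed = 1,
                                  noise_sd = 0.05) {
  withr::with_seed(seed, {
    x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
    noise <- matrix(runif(n * n_noise), n)
    colnames(noise) <- sprintf("noise%02d", seq_len(n_noise))
    y <- x1 + 0.9 * x2 + 0.8 * x3 + rnorm(n, 0, noise_sd)
  })
  tibble::tibble(ppc_g_per_kg = y, info1 = x1, info2 = x2, info3 = x3,
                 !!!tibble::as_tibble(noise))
}

# Deterministic scene configuration: no stochastic term anywhere.
noiseless_model <- function(...) {
  args <- utils::modifyList(list(noise_sd_reflectance = 0, noise_sd_ppc = 0,
                                 texture_amp = 0, texture_corr_sd = 0),
                            list(...))
  do.call(canopy_model, args)
}

small_layout <- function() {
  field_layout(plot_shape_px = c(12L, 16L), gap_px = 2L)
}

random_patch <- function(nr, nc, levels, seed) {
  withr::with_seed(seed, {
    matrix(sample(0:(levels - 1), nr * nc, replace = TRUE), nr, nc)
  })
}
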