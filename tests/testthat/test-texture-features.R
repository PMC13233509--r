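test_that("quantization maps min-max linearly onto the grey bins", {
  two <- quantize(matrix(c(0, 1, 0, 1), 2, 2), glcm_spec(levels = 2))
  expect_setequal(as.integer(two), c(0L, 1L))

  withr::with_seed(3, u <- matrix(runif(400), 20, 20))
  q <- quantize(u, glcm_spec(levels = 64))
  expect_equal(max(q), 63L); expect_equal(min(q), 0L)
  expect_equal(q[which.max(u)], 63L)

  # invariant to affine rescaling of the band
  expect_identical(quantize(3 * u + 7, glcm_spec(levels = 64)), q)

  expect_warning(qc <- quantize(matrix(5, 3, 3), glcm_spec()), "constant")
  expect_true(all(qc == 0L))
})

test_that("glcm_stats matches the closed-form degenerate cases", {
  # constant patch: single co-occurrence cell
  st <- glcm_stats(matrix(7L, 4, 4), glcm_spec(levels = 64))
  expect_equal(unname(st),
               c(7, 0, 1, 0, 0, 0, 1, 0), tolerance = 1e-12)

  # checkerboard, horizontal direction only: P(0,1) = P(1,0) = 0.5
  cb <- (outer(1:4, 1:4, `+`) %% 2L)
  storage.mode(cb) <- "integer"
  spec <- glcm_spec(levels = 2)
  spec$offsets <- list(`0` = c(0L, 1L))
  st <- glcm_stats(cb, spec)
  expect_equal(unname(st),
               c(0.5, 0.25, 0.5, 1, 1, log(2), 0.5, -1), tolerance = 1e-12)
})

test_that("glcm_stats equals the brute-force pair-enumeration oracle", {
  for (s in 1:60) {
    lv <- sample(c(2L, 4L, 8L), 1)
    p <- random_patch(sample(3:6, 1), sample(3:6, 1), lv, s)
    got <- glcm_stats(p, glcm_spec(levels = lv))
    want <- oracle_glcm_stats(p, levels = lv)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("dissimilarity is Cauchy-Schwarz bounded by contrast", {
  for (s in 1:40) {
    p <- random_patch(6, 6, 8, 1000 + s)
    st <- glcm_stats(p, glcm_spec(levels = 8))
    expect_lte(st[["Dis"]]^2, st[["Con"]] + 1e-12)
  }
})

test_that("texture maps honour the moving-window contract", {
  cst <- matrix(0.5, 8, 8)
  expect_warning(maps <- texture_maps(cst, glcm_spec()), "constant")
  inner <- maps$Ent[2:7, 2:7]
  expect_true(all(inner == 0))
  expect_true(all(maps$Hom[2:7, 2:7] == 1))
  expect_true(all(is.na(maps$Ent[1, ])))  # border is missing

  withr::with_seed(9, b <- matrix(runif(20 * 15), 20, 15))
  spec <- glcm_spec(levels = 8)
  maps <- texture_maps(b, spec)

  # any interior pixel equals glcm_stats of its extracted window
  q <- quantize(b, spec)
  for (rc in list(c(5, 5), c(10, 7), c(19, 14))) {
    w <- q[(rc[1] - 1):(rc[1] + 1), (rc[2] - 1):(rc[2] + 1)]
    expect_equal(vapply(maps, function(m) m[rc[1], rc[2]], numeric(1)),
                 glcm_stats(w, spec), tolerance = 1e-12)
  }

  # transposing the input transposes every output map (0/90 and 45/135 swap)
  maps_t <- texture_maps(t(b), spec)
  for (k in names(maps)) {
    expect_equal(maps[[k]], t(maps_t[[k]]), tolerance = 1e-12)
  }

  expect_error(texture_maps(matrix(1, 2, 2), glcm_spec()), "smaller")
})

test_that("aggregation yields 8 features per band with the field naming", {
  m <- noiseless_model(texture_amp = 0.1, texture_corr_sd = 0.05)
  lay <- small_layout()
  tr <- simulate_ppc_truth(lay, m, "T1", seed = 4)
  sc <- simulate_scene(lay, tr, m, seed = 4)
  spec <- glcm_spec()
  maps <- purrr::map(setNames(seq_along(sc$band_nm),
                              as.character(sc$band_nm)),
                     ~ texture_maps(sc$reflectance[, , .x], spec))
  tf <- aggregate_textures(maps, sc$plot_masks[[1]])
  expect_equal(ncol(tf), 48L)  # 8 stats x 6 bands
  expect_true(all(c("450-Mea", "750-Mea", "840-Mea", "450-Ent") %in% names(tf)))

  tf1 <- aggregate_textures(maps["450"], sc$plot_masks[[1]])
  expect_equal(ncol(tf1), 8L)

  expect_error(aggregate_textures(maps, matrix(FALSE, 2, 2)), "empty")
})

test_that("texture indices obey their defining algebra", {
  tf <- tibble::tibble(`450-Ent` = 3, `750-Mea` = 1, `840-Mea` = 4)
  # self-pair identities under a listed policy
  self <- texture_indices(tf, pairs = data.frame(t1 = "450-Ent",
                                                 t2 = "450-Ent"))
  expect_equal(self[["NDTI(450-Ent,450-Ent)"]], 0)
  expect_equal(self[["RTI(450-Ent,450-Ent)"]], 1)
  expect_equal(self[["DTI(450-Ent,450-Ent)"]], 0)

  # direct arithmetic, T1 = 3, T2 = 1
  ti <- texture_indices(tf)
  expect_equal(ti[["NDTI(450-Ent,750-Mea)"]], 0.5)
  expect_equal(ti[["RTI(450-Ent,750-Mea)"]], 3)
  expect_equal(ti[["DTI(450-Ent,750-Mea)"]], 2)

  # swapping the pair negates NDTI/DTI and inverts RTI
  expect_equal(ti[["NDTI(750-Mea,450-Ent)"]], -0.5)
  expect_equal(ti[["DTI(750-Mea,450-Ent)"]], -2)
  expect_equal(ti[["RTI(450-Ent,750-Mea)"]] * ti[["RTI(750-Mea,450-Ent)"]], 1)

  # all ordered distinct pairs: k*(k-1) per family
  k <- 3
  expect_equal(sum(grepl("^NDTI\\(", names(ti))), k * (k - 1))
  expect_equal(sum(grepl("^RTI\\(", names(ti))), k * (k - 1))
  expect_equal(sum(grepl("^DTI\\(", names(ti))), k * (k - 1))

  # zero denominator yields NA
  tf0 <- tibble::tibble(`450-Ent` = 1, `750-Mea` = 0)
  ti0 <- texture_indices(tf0)
  expect_true(is.na(ti0[["RTI(450-Ent,750-Mea)"]]))
  expect_error(texture_indices(tf, pairs = data.frame(t1 = "nope", t2 = "x")),
               "unknown texture features")
})
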