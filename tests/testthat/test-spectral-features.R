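test_that("colour indices match hand arithmetic and the grey-pixel symmetry", {
  grey <- color_indices(tibble::tibble(R = 100, G = 100, B = 100))
  expect_equal(grey$r, 1 / 3); expect_equal(grey$g, 1 / 3)
  expect_equal(grey$GRI, 1); expect_equal(grey$BGI, 1); expect_equal(grey$BRI, 1)
  expect_equal(grey$CI_GRVI, 0); expect_equal(grey$VARI, 0)
  expect_equal(grey$MGRVI, 0); expect_equal(grey$RGBVI, 0)
  expect_equal(grey$TGI, 40)  # -0.5*(190*0 - 120*(2/3))

  x <- color_indices(tibble::tibble(R = 50, G = 100, B = 50))
  expect_equal(x$g, 0.5); expect_equal(x$r, 0.25); expect_equal(x$b, 0.25)
  expect_equal(x$GRI, 2); expect_equal(x$CI_GRVI, (0.5 - 0.25) / 0.75)

  # exactly the 14 colour-index columns are defined
  expect_true(all(uavppc:::ci_feature_names() %in% names(x)))
  expect_length(uavppc:::ci_feature_names(), 14L)

  # TGI literature variant uses (r - b)
  x2 <- color_indices(tibble::tibble(R = 50, G = 100, B = 50),
                      strict_printed_formulas = FALSE)
  expect_equal(x2$TGI, -0.5 * (190 * (0.25 - 0.5) - 120 * (0.25 - 0.25)))
})

test_that("normalized shares always sum to one for positive DN triples", {
  withr::with_seed(7, {
    df <- tibble::tibble(R = runif(100, 1, 255), G = runif(100, 1, 255),
                         B = runif(100, 1, 255))
  })
  ci <- color_indices(df)
  expect_equal(ci$r + ci$g + ci$b, rep(1, 100), tolerance = 1e-12)
  nd <- c("CI_GRVI", "MGRVI", "RGBVI")
  for (f in nd) expect_true(all(abs(ci[[f]]) <= 1))
})

test_that("vegetation indices match hand arithmetic and equality cases", {
  base <- tibble::tibble(R450 = 0.05, R555 = 0.1, R660 = 0.1, R720 = 0.4,
                         R750 = 0.45, R840 = 0.5)
  vi <- vegetation_indices(base)
  expect_equal(vi$NDVI, (0.5 - 0.1) / 0.6)
  expect_equal(vi$DVI, 0.4)
  expect_equal(vi$RVI, 5)
  expect_equal(vi$OSAVI, 1.16 * 0.4 / 0.76)
  expect_equal(vi$MTCI, (0.5 - 0.4) / (0.4 - 0.1))
  expect_equal(vi$CI_red_edge, 0.25)
  expect_length(uavppc:::vi_feature_names(), 12L)
  expect_true(all(uavppc:::vi_feature_names() %in% names(vi)))

  eq <- vegetation_indices(tibble::tibble(R450 = 0.1, R555 = 0.1, R660 = 0.5,
                                          R720 = 0.5, R750 = 0.5, R840 = 0.5))
  expect_equal(eq$NDVI, 0); expect_equal(eq$NDRE, 0)
  expect_equal(eq$CI_red_edge, 0)

  # the two red-edge configurations agree when the bands coincide
  b2 <- base; b2$R750 <- b2$R720
  expect_equal(vegetation_indices(b2, red_edge = "750"),
               vegetation_indices(b2, red_edge = "720"))

  # zero denominators become NA, never infinities
  z <- vegetation_indices(tibble::tibble(R450 = 0, R555 = 0, R660 = 0,
                                         R720 = 0, R750 = 0, R840 = 0))
  expect_true(is.na(z$NDVI) && is.na(z$RVI) && is.na(z$MTCI))
})

test_that("NDVI maps handle constants, guards and soil/vegetation contrast", {
  st <- band_stack(list(`660` = matrix(0.1, 4, 4), `840` = matrix(0.5, 4, 4)))
  expect_equal(unique(as.numeric(ndvi_map(st))), 2 / 3)

  zero <- band_stack(list(`660` = matrix(0, 2, 2), `840` = matrix(0, 2, 2)))
  expect_true(all(is.na(ndvi_map(zero))))

  expect_error(ndvi_map(band_stack(list(`450` = matrix(1, 2, 2)))), "660")

  # vegetated plots sit above the soil background
  m <- noiseless_model()
  lay <- small_layout()
  tr <- simulate_ppc_truth(lay, m, "T1", seed = 1)
  sc <- simulate_scene(lay, tr, m, seed = 1)
  nd <- ndvi_map(sc)
  veg <- Reduce(`|`, sc$plot_masks)
  expect_gt(mean(nd[veg]), mean(nd[!veg]))
})

test_that("dimidiate-pixel FVC honours endpoints, linearity and clipping", {
  pars <- fvc_params(ndvi_soil = 0.2, ndvi_veg = 0.8)
  mk <- function(v) matrix(v, 2, 2)
  all_mask <- matrix(TRUE, 2, 2)
  expect_equal(fvc(mk(0.2), all_mask, pars), 0)
  expect_equal(fvc(mk(0.8), all_mask, pars), 1)
  expect_equal(fvc(mk(0.5), all_mask, pars), 0.5)
  expect_equal(fvc(mk(0.05), all_mask, pars), 0)  # clipped below soil
  expect_equal(fvc(mk(0.95), all_mask, pars), 1)  # clipped above veg

  # monotone in pixel NDVI
  expect_gt(fvc(mk(0.6), all_mask, pars), fvc(mk(0.4), all_mask, pars))

  # affine rescaling of the NDVI axis applied consistently changes nothing
  a <- 2.5; b <- -0.3
  pars2 <- fvc_params(ndvi_soil = a * 0.2 + b, ndvi_veg = a * 0.8 + b)
  expect_equal(fvc(mk(a * 0.5 + b), all_mask, pars2),
               fvc(mk(0.5), all_mask, pars))

  expect_error(fvc(mk(0.5), all_mask, fvc_params()), "degenerate")
  expect_error(fvc_params(ndvi_soil = 0.8, ndvi_veg = 0.2), "below")
})
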