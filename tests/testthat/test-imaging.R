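# I/O, boundary derivation, and the preprocessing chain.

test_that("PNG round trip scales intensities to [0,1] and binarizes masks", {
  dir <- withr::local_tempdir()
  img <- matrix(seq(0, 1, length.out = 24 * 24), 24, 24)
  img[1, 1] <- 1  # a true 255 pixel
  msk <- matrix(0, 24, 24); msk[5:10, 5:10] <- 1
  EBImage::writeImage(sgbnet:::arr_to_ebi(img), file.path(dir, "i.png"))
  EBImage::writeImage(sgbnet:::arr_to_ebi(msk), file.path(dir, "m.png"))
  s <- load_sample(file.path(dir, "i.png"), file.path(dir, "m.png"))
  expect_equal(dim(s$image)[1:2], dim(s$vessel_mask))
  expect_equal(max(s$image), 1.0)             # 255 -> 1.0
  expect_setequal(unique(as.vector(s$vessel_mask)), c(0, 1))
  expect_equal(s$vessel_mask, msk)            # {0,255} png -> {0,1}
  expect_true(all(s$fov_mask == 1))           # absent FOV -> all ones
  # shape mismatch is a validation error
  EBImage::writeImage(sgbnet:::arr_to_ebi(matrix(0, 10, 10)),
                      file.path(dir, "bad.png"))
  expect_error(load_sample(file.path(dir, "i.png"), file.path(dir, "bad.png")),
               "shapes differ")
  expect_error(load_sample(file.path(dir, "nope.png"), file.path(dir, "m.png")),
               "nope.png")
  expect_error(sgbnet:::read_raster(file.path(dir, "x.gif")), "GIF")
})

test_that("boundary mask is the morphological gradient (oracle + worked cases)", {
  expect_equal(derive_boundary(matrix(0, 8, 8)), matrix(0, 8, 8))
  # all-ones mask: gradient only along the grid border (outside = background)
  b <- derive_boundary(matrix(1, 8, 8))
  expect_true(all(b[2:7, 2:7] == 0))
  expect_true(all(b[1, ] == 1) && all(b[8, ] == 1))
  # centered 3x3 square in 5x5
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  expect_equal(derive_boundary(m), oracle_morph_gradient(m))
  expect_error(derive_boundary(matrix(0.5, 4, 4)), "binary")
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rbinom(16 * 16, 1, runif(1, .1, .6)), 16, 16)
    expect_equal(derive_boundary(m), oracle_morph_gradient(m))
  }
})

test_that("boundary pixels touch vessels (subset of 1-px dilation)", {
  s <- synth_fundus(synth_params(seed = 3, size = c(96, 96)))
  dil <- oracle_morph_gradient(s$vessel_mask) + s$vessel_mask  # dilation >= mask
  expect_true(all(s$boundary_mask <= (dil > 0)))
})

test_that("preprocessing follows gray -> equalize -> gamma and keeps masks", {
  s <- synth_fundus(synth_params(seed = 2, size = c(96, 96)))
  # identity chain
  id <- preprocess(s, preprocess_config(hist_eq = "none", gamma = 1))
  expect_equal(id$image, s$image)
  expect_identical(id$vessel_mask, s$vessel_mask)
  expect_identical(id$fov_mask, s$fov_mask)
  # gamma closed form
  s2 <- s; s2$image <- matrix(0.25, 96, 96)
  g <- preprocess(s2, preprocess_config(hist_eq = "none", gamma = 0.5))
  expect_equal(g$image[1, 1], 0.5, tolerance = 1e-12)
  # constant image through global equalization stays constant
  eq <- preprocess(s2, preprocess_config(hist_eq = "global", gamma = 1))
  expect_lt(diff(range(eq$image)), 1e-12)
  # full default chain stays in range, single channel, masks untouched
  p <- preprocess(s)
  expect_true(all(p$image >= 0 & p$image <= 1))
  expect_equal(length(dim(p$image)), 2L)
  expect_identical(p$vessel_mask, s$vessel_mask)
  expect_error(preprocess_config(gamma = 0), "positive")
})

test_that("RGB input is reduced to luminance before equalization", {
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  s <- fundus_sample(img, matrix(0, 48, 48), sample_id = "rgb")
  p <- preprocess(s, preprocess_config(hist_eq = "none", gamma = 1))
  expect_equal(p$image, 0.2989 * img[, , 1] + 0.5870 * img[, , 2] +
                 0.1140 * img[, , 3], tolerance = 1e-12)
})

test_that("manifest write/read round-trips samples", {
  dir <- withr::local_tempdir()
  ss <- list(synth_fundus(synth_params(seed = 1, size = c(64, 64))),
             synth_fundus(synth_params(seed = 2, size = c(64, 64))))
  mf <- write_manifest(ss, dir)
  back <- read_manifest(mf)
  expect_length(back, 2)
  expect_equal(back[[1]]$vessel_mask, ss[[1]]$vessel_mask)
  expect_equal(back[[2]]$fov_mask, ss[[2]]$fov_mask)
  expect_lt(max(abs(back[[1]]$image - ss[[1]]$image)), 1 / 255)
})
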