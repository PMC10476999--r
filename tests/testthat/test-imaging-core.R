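test_that("ct_image validates shape, finiteness and domain", {
  expect_error(ct_image(matrix(0, 4, 4)), "8 x 8")
  expect_error(ct_image(matrix(c(NaN, rnorm(63)), 8, 8)), "finite")
  expect_error(ct_image(matrix(0, 8, 8), domain = "VOLTS"))
  im <- ct_image(matrix(rnorm(64), 8, 8), pixel_spacing = 0.7)
  expect_s3_class(im, "ct_image")
  expect_identical(dim(im), c(8L, 8L))
})

test_that("normalize/denormalize are exact affine inverses", {
  s <- norm_stats(mean = 40, std = 400)
  im <- ct_image(matrix(rnorm(256, 40, 300), 16, 16))
  rt <- denormalize_ct(normalize_ct(im, s), s)
  expect_lt(max(abs(rt$pixels - im$pixels)), 1e-9)
  expect_identical(rt$domain, "HU")

  # centering identity and simple affine arithmetic
  mu <- 123.4
  const <- ct_image(matrix(mu, 8, 8))
  expect_true(all(normalize_ct(const, norm_stats(mu, 5))$pixels == 0))
  two <- ct_image(matrix(c(0, 100), 8, 8))
  zn <- normalize_ct(two, norm_stats(50, 50))
  expect_equal(sort(unique(as.vector(zn$pixels))), c(-1, 1))
  zeros <- ct_image(matrix(0, 8, 8), domain = "NORMALIZED")
  expect_true(all(denormalize_ct(zeros, norm_stats(40, 400))$pixels == 40))
  pm <- ct_image(matrix(c(-1, 1), 8, 8), domain = "NORMALIZED")
  expect_equal(range(denormalize_ct(pm, norm_stats(0, 1000))$pixels), c(-1000, 1000))
  expect_error(norm_stats(0, 0), "positive")
})

test_that("dataset-level and per-image normalization stats", {
  ims <- list(ct_image(matrix(rnorm(64, 0, 10), 8, 8)),
              ct_image(matrix(rnorm(64, 100, 10), 8, 8)))
  pooled <- compute_normalization_stats(ims)
  expect_equal(pooled$mean, mean(c(ims[[1]]$pixels, ims[[2]]$pixels)))
  per <- compute_normalization_stats(ims, per_image = TRUE)
  expect_length(per, 2)
  expect_equal(per[[1]]$mean, mean(ims[[1]]$pixels))
})

test_that("display window maps the HU interval linearly with clipping", {
  vals <- matrix(c(-500, -160, 40, 240, 1000, rep(0, 59)), 8, 8)
  w <- apply_display_window(ct_image(vals), -160, 240)
  expect_equal(w$pixels[1, 1], 0)     # below window clips to 0
  expect_equal(w$pixels[2, 1], 0)     # low bound
  expect_equal(w$pixels[3, 1], 0.5)   # window midpoint
  expect_equal(w$pixels[4, 1], 1)     # high bound
  expect_equal(w$pixels[5, 1], 1)     # above window clips to 1
  expect_error(apply_display_window(ct_image(vals), 100, 100), "width")

  # monotone non-decreasing in the input value
  ramp <- ct_image(matrix(seq(-2000, 3000, length.out = 64), 8, 8))
  wr <- apply_display_window(ramp, -160, 240)
  expect_true(all(diff(as.vector(wr$pixels)) >= 0))
})

test_that("array container round trip is bit-identical", {
  im <- ct_image(matrix(rnorm(64 * 64, 40, 350), 64, 64),
                 domain = "HU", pixel_spacing = 0.66)
  path <- withr::local_tempfile(fileext = ".ctarr")
  write_ct_image(im, path)
  back <- read_ct_image(path)
  expect_identical(back$pixels, im$pixels)
  expect_identical(back$domain, im$domain)
  expect_identical(back$pixel_spacing, im$pixel_spacing)
})

test_that("16-bit TIFF round trip is exact to the quantization step", {
  im <- ct_image(matrix(runif(256, -1000, 2000), 16, 16))
  path <- withr::local_tempfile(fileext = ".tif")
  write_ct_image(im, path, format = "tiff16")
  back <- read_ct_image(path)
  expect_lt(max(abs(back$pixels - im$pixels)), 0.5 + 1e-6)  # half a HU step
})

test_that("reading bad inputs errors with the path in the message", {
  expect_error(read_ct_image("/nonexistent/file.ctarr"), "nonexistent")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), path, bits.per.sample = 16L)
  expect_error(read_ct_image(path), "minimum size")
})
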