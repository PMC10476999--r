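test_that("HU/attenuation conversions follow the water calibration", {
  mu_w <- 0.0206
  im <- ct_image(matrix(c(0, -1000, 1000, rep(40, 61)), 8, 8))
  att <- hu_to_attenuation(im, mu_w)
  expect_equal(att$pixels[1, 1], mu_w)        # water
  expect_equal(att$pixels[2, 1], 0)           # air
  expect_equal(att$pixels[3, 1], 2 * mu_w)
  # round trip identity for HU >= -1000
  back <- attenuation_to_hu(att, mu_w)
  expect_equal(back$pixels, im$pixels, tolerance = 1e-9)
})

test_that("radon transform is linear with the right geometry", {
  z <- ct_image(matrix(0, 32, 32), domain = "ATTENUATION")
  expect_true(all(radon_transform(z, 12)$values == 0))

  # unit-attenuation axis-aligned square, central vertical ray: integral = side
  side <- 20L
  sq <- matrix(0, 64, 64)
  sq[23:(22 + side), 23:(22 + side)] <- 1
  sino <- radon_transform(ct_image(sq, domain = "ATTENUATION"), 2)
  centre <- (ncol(sino$values) + 1) / 2
  expect_equal(sino$values[1, centre], side, tolerance = 0.75)

  # linearity
  x <- ct_image(matrix(runif(1024), 32, 32), domain = "ATTENUATION")
  s1 <- radon_transform(x, 10)$values
  x3 <- x; x3$pixels <- 3 * x$pixels
  expect_equal(radon_transform(x3, 10)$values, 3 * s1, tolerance = 1e-9)
})

test_that("projections of a smooth disk are rotation invariant", {
  ph <- smooth_attenuation_phantom(64)
  sino <- radon_transform(ph, 24)
  profs <- sino$values
  ref <- profs[1, ]
  dev <- apply(profs, 1, function(p) max(abs(p - ref)))
  expect_lt(max(dev) / max(ref), 0.01)
  # sinogram mass is conserved across angles
  mass <- rowSums(profs)
  expect_lt(diff(range(mass)) / mean(mass), 0.01)
})

test_that("quantum noise is Poisson-dispersed with the right mean", {
  p0 <- 1
  n0 <- 500 / exp(-p0)  # rate 500 per bin
  sino <- sinogram(matrix(p0, 200, 500), angles = seq(0, pi, length.out = 201)[1:200])
  noisy <- add_quantum_noise(sino, dose_model(N0 = n0, dose_fraction = 1, seed = 99))
  counts <- as.vector(noisy$values)
  expect_equal(mean(counts), 500, tolerance = 3 * sqrt(500 / length(counts)) / 500)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
  # reproducibility
  noisy2 <- add_quantum_noise(sino, dose_model(N0 = n0, dose_fraction = 1, seed = 99))
  expect_identical(noisy$values, noisy2$values)
})

test_that("log conversion inverts the counting model", {
  p <- matrix(runif(80, 0, 4), 8, 10)
  dm <- dose_model(N0 = 1e6, dose_fraction = 0.5, K = 2, seed = 1)
  n0e <- 1e6 * 0.5
  noiseless <- sinogram(2 * n0e * exp(-p), angles = seq_len(8) * pi / 8 - pi / 8,
                        domain = "COUNTS")
  rec <- counts_to_line_integrals(noiseless, dm)
  expect_equal(rec$values, p, tolerance = 1e-12)
  # zero counts hit the photon-starvation floor, stay finite
  zero <- sinogram(matrix(0, 8, 10), angles = seq_len(8) * pi / 8 - pi / 8,
                   domain = "COUNTS")
  recz <- counts_to_line_integrals(zero, dm)
  expect_true(all(is.finite(recz$values)))
  expect_equal(max(recz$values), log(n0e))
  # high-dose round trip through the noise model recovers p
  dm9 <- dose_model(N0 = 1e9, dose_fraction = 1, seed = 5)
  rt <- counts_to_line_integrals(add_quantum_noise(
    sinogram(p, angles = seq_len(8) * pi / 8 - pi / 8), dm9), dm9)
  expect_lt(max(abs(rt$values - p)), 1e-3)
})

test_that("FBP is linear and inverts the radon transform on smooth images", {
  ph <- smooth_attenuation_phantom(128)
  sino <- radon_transform(ph, 180)
  rec <- fbp(sino, output_size = 128)
  xs <- (1:128 - 64.5) / 64
  circ <- outer(xs^2, xs^2, `+`) <= 0.7^2
  rel_rmse <- sqrt(mean((rec$pixels[circ] - ph$pixels[circ])^2)) /
    sqrt(mean(ph$pixels[circ]^2))
  expect_lt(rel_rmse, 0.05)

  # linearity and zero input
  s2 <- sino; s2$values <- 2.5 * sino$values
  expect_equal(fbp(s2, output_size = 32)$pixels,
               2.5 * fbp(sino, output_size = 32)$pixels, tolerance = 1e-9)
  zs <- sino; zs$values <- 0 * sino$values
  expect_true(all(fbp(zs, output_size = 32)$pixels == 0))
  expect_warning(fbp(sinogram(matrix(1, 4, 16), angles = (0:3) * pi / 4)),
                 "degraded")
})

test_that("simulate_ldct is seed-deterministic and dose-monotone", {
  ph <- generate_phantom(phantom_spec(size = 64))
  a <- simulate_ldct(ph, dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 3),
                     n_angles = 60)
  b <- simulate_ldct(ph, dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 3),
                     n_angles = 60)
  expect_identical(a$pixels, b$pixels)

  # reference: the noiseless radon/fbp round trip
  att <- hu_to_attenuation(ph)
  ref <- attenuation_to_hu(fbp(radon_transform(att, 60), output_size = 64))
  full <- simulate_ldct(ph, dose_model(N0 = 1e9, dose_fraction = 1, seed = 3),
                        n_angles = 60)
  quarter <- simulate_ldct(ph, dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 3),
                           n_angles = 60)
  dr <- diff(range(ref$pixels))
  expect_gt(psnr(full, ref, dr), psnr(quarter, ref, dr))
})

test_that("image-domain noise std scales down with dose and N0", {
  ph <- generate_phantom(phantom_spec(size = 64))
  sds <- vapply(c(0.1, 0.25, 0.5, 1.0), function(df) {
    ld <- inject_image_noise(ph, dose_model(N0 = 1e5, dose_fraction = df, seed = 17))
    sd(ld$pixels - ph$pixels)
  }, 0.0)
  expect_true(all(diff(sds) < 0))

  # three-decade N0 sweep through the projection simulator
  sds_n0 <- vapply(c(1e4, 1e5, 1e6, 1e7), function(n0) {
    ld <- simulate_ldct(ph, dose_model(N0 = n0, dose_fraction = 1, seed = 8),
                        n_angles = 45)
    sd(ld$pixels[28:36, 40:48])
  }, 0.0)
  expect_true(all(diff(sds_n0) < 0))

  # large-count limit: noise vanishes
  hi <- inject_image_noise(ph, dose_model(N0 = 1e10, dose_fraction = 1, seed = 2))
  expect_lt(max(abs(hi$pixels - ph$pixels)), 0.5)
  # determinism
  n1 <- inject_image_noise(ph, dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 4))
  n2 <- inject_image_noise(ph, dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 4))
  expect_identical(n1$pixels, n2$pixels)
})
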