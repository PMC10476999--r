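test_that("hybrid loss decomposes exactly into its weighted components", {
  set.seed(31)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  wc <- weight_config(2, 2)
  for (k in 1:20) {
    a1 <- runif(1, 0, 5); a2 <- runif(1, 0, 5)
    if (a1 + a2 == 0) a1 <- 1
    r <- hybrid_loss(x, y, hybrid_config(a1, a2, weight_config = wc))
    expect_identical(r$hybrid_loss, a1 * r$wp_loss + a2 * r$hf_loss)
    expect_equal(r$wp_loss, wp_loss(x, y, wc))
    expect_equal(r$hf_loss, hf_loss(x, y, r0 = 0.1))
  }
  # degenerate alphas
  r10 <- hybrid_loss(x, y, hybrid_config(3, 0, weight_config = wc))
  expect_identical(r10$hybrid_loss, 3 * r10$wp_loss)
  r01 <- hybrid_loss(x, y, hybrid_config(0, 2, weight_config = wc))
  expect_identical(r01$hybrid_loss, 2 * r01$hf_loss)
  expect_error(hybrid_config(0, 0), "positive")
})

test_that("hybrid loss is positively 1-homogeneous", {
  set.seed(32)
  x <- matrix(rnorm(144), 12, 12)
  y <- matrix(rnorm(144), 12, 12)
  cfg <- hybrid_config(weight_config = weight_config(3, 3))
  h1 <- hybrid_loss(x, y, cfg)$hybrid_loss
  for (a in c(0.05, 3, 250))
    expect_equal(hybrid_loss(a * x, a * y, cfg)$hybrid_loss, a * h1)
})

test_that("hybrid fixture combines the two module oracles", {
  fx <- patch_mae_fixture(1:4)
  cfg <- hybrid_config(1, 1, weight_config = weight_config(2, 2), r0 = 0.2)
  r <- hybrid_loss(fx$generated, fx$target, cfg)
  expect_equal(r$wp_loss, 12.0)
  expect_equal(r$hybrid_loss,
               12.0 + oracle_hf_loss(fx$generated, fx$target, 0.2),
               tolerance = 1e-9)
})

test_that("analytic gradients match finite differences with weights frozen", {
  set.seed(33)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  wc <- weight_config(2, 2)
  cfg <- hybrid_config(weight_config = wc)

  # frozen-weight hybrid closure: the constant-weight contract
  w0 <- compute_patch_weights(
    vapply(partition_patches(x, y, wc),
           function(p) mean(abs(p$generated - p$target)), 0.0), wc)
  frozen <- function(z) {
    maes <- vapply(partition_patches(z, y, wc),
                   function(p) mean(abs(p$generated - p$target)), 0.0)
    sum(w0 * maes) + hf_loss(z, y, r0 = 0.1)
  }
  fd <- fd_gradient(frozen, x)
  an <- hybrid_loss_grad(x, y, cfg)
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-4)

  # WPLoss alone under the same frozen-weight contract
  fd_wp <- fd_gradient(function(z) {
    maes <- vapply(partition_patches(z, y, wc),
                   function(p) mean(abs(p$generated - p$target)), 0.0)
    sum(w0 * maes)
  }, x)
  expect_lt(max(abs(wp_loss_grad(x, y, wc) - fd_wp)) / max(abs(fd_wp)), 1e-4)

  # HF gradient, both distances
  fd_hf <- fd_gradient(function(z) hf_loss(z, y, r0 = 0.1), x)
  expect_lt(max(abs(hf_loss_grad(x, y, r0 = 0.1) - fd_hf)) / max(abs(fd_hf)), 1e-4)
  fd_hf2 <- fd_gradient(function(z) hf_loss(z, y, r0 = 0.1, distance = "l2"), x)
  expect_lt(max(abs(hf_loss_grad(x, y, r0 = 0.1, distance = "l2") - fd_hf2)) /
              max(abs(fd_hf2)), 1e-4)
})

test_that("loss reports serialize to JSON with their invariant intact", {
  fx <- patch_mae_fixture(1:4)
  r <- hybrid_loss(fx$generated, fx$target,
                   hybrid_config(2, 0.5, weight_config = weight_config(2, 2)))
  expect_identical(r$hybrid_loss, 2 * r$wp_loss + 0.5 * r$hf_loss)
  parsed <- jsonlite::fromJSON(loss_report_json(r))
  expect_equal(parsed$wp_loss, r$wp_loss)
  expect_equal(parsed$patch_grid$weight, c(0.4, 0.8, 1.2, 1.6))
})
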