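small_data <- function() {
  d <- demo_dataset()
  list(train = d$train[1:4], val = d$val[1:2], test = d$test[1:2])
}

test_that("denoiser initialization is deterministic with the configured std", {
  cfg <- train_config(seed = 9, init_std = 0.01)
  n1 <- build_denoiser(cfg)
  n2 <- build_denoiser(cfg)
  expect_identical(ldctloss:::.net_param_vector(n1),
                   ldctloss:::.net_param_vector(n2))
  w <- unlist(lapply(n1$layers, function(l) as.vector(l$W)))
  expect_lt(abs(sd(w) - 0.01) / 0.01, 0.10)
  expect_false(identical(ldctloss:::.net_param_vector(n1),
                         ldctloss:::.net_param_vector(build_denoiser(
                           train_config(seed = 10)))))

  # small-weight init: residual model is near the identity
  x <- matrix(rnorm(64 * 64), 64, 64)
  out <- ldctloss:::.net_forward(n1, x)$output
  expect_lt(max(abs(out - x)), 0.5)
})

test_that("network backward pass matches finite differences", {
  set.seed(51)
  net <- ldctloss:::.net_init(seed = 3, init_std = 0.1, channels = 3L, depth = 3L)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  loss_fn <- function(n) {
    out <- ldctloss:::.net_forward(n, x)$output
    mean((out - y)^2)
  }
  fwd <- ldctloss:::.net_forward(net, x, keep_cache = TRUE)
  gout <- 2 * (fwd$output - y) / length(y)
  grads <- ldctloss:::.net_backward(net, fwd, gout)
  h <- 1e-6
  for (l in seq_along(net$layers)) {
    idx <- cbind(sample(dim(net$layers[[l]]$W)[1], 4, replace = TRUE),
                 sample(dim(net$layers[[l]]$W)[2], 4, replace = TRUE),
                 sample(dim(net$layers[[l]]$W)[3], 4, replace = TRUE),
                 sample(dim(net$layers[[l]]$W)[4], 4, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      np <- net; nm <- net
      np$layers[[l]]$W[idx[r, , drop = FALSE]] <-
        np$layers[[l]]$W[idx[r, , drop = FALSE]] + h
      nm$layers[[l]]$W[idx[r, , drop = FALSE]] <-
        nm$layers[[l]]$W[idx[r, , drop = FALSE]] - h
      fd <- (loss_fn(np) - loss_fn(nm)) / (2 * h)
      expect_equal(grads[[l]]$W[idx[r, , drop = FALSE]], fd, tolerance = 1e-4)
    }
  }
})

test_that("hybrid loss drives a nonzero gradient into the parameters", {
  set.seed(52)
  net <- ldctloss:::.net_init(seed = 4, init_std = 0.01, channels = 4L, depth = 3L)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  fwd <- ldctloss:::.net_forward(net, x, keep_cache = TRUE)
  g <- hybrid_loss_grad(fwd$output, y,
                        hybrid_config(weight_config = weight_config(2, 2)))
  grads <- ldctloss:::.net_backward(net, fwd, g)
  gnorm <- sum(unlist(lapply(grads, function(gl) sum(gl$W^2) + sum(gl$b^2))))
  expect_gt(gnorm, 0)
})

test_that("training reduces the loss reproducibly with the lr schedule", {
  data <- small_data()
  cfg <- train_config(loss = "hybrid", epochs = 6, learning_rate = 1e-3,
                      batch_size = 1, lr_halving_interval = 2, seed = 13)
  fit1 <- train_denoiser(data, cfg)
  fit2 <- train_denoiser(data, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(coef(fit1), coef(fit2))
  expect_lt(fit1$history$train_loss[6], fit1$history$train_loss[1])
  # halving every 2 epochs: lr pattern l, l, l/2, l/2, l/4, l/4
  expect_equal(fit1$history$lr, 1e-3 * c(1, 1, 0.5, 0.5, 0.25, 0.25))
  expect_error(train_denoiser(list(train = list()), cfg), "empty")
})

test_that("denoise preserves shape and domain and is deterministic", {
  data <- small_data()
  fit <- train_denoiser(data, train_config(loss = "mae", epochs = 2,
                                           learning_rate = 1e-3, seed = 1))
  ld <- data$test[[1]]$ldct
  out1 <- denoise(fit, ld)
  out2 <- predict(fit, ld)
  expect_identical(out1$pixels, out2$pixels)
  expect_identical(dim(out1$pixels), dim(ld$pixels))
  expect_identical(out1$domain, "HU")
  lst <- predict(fit, list(ld, ld))
  expect_length(lst, 2)
})

test_that("model methods print, summarize, plot and expose coefficients", {
  data <- small_data()
  fit <- train_denoiser(data, train_config(epochs = 2, seed = 2))
  expect_output(print(fit), "Residual CT denoiser")
  expect_output(summary(fit), "normalization")
  expect_type(coef(fit), "double")
  pdf(NULL)
  expect_no_error(plot(fit))
  dev.off()
})

test_that("ablation table has the documented schema and shared-seed rows", {
  data <- small_data()
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- ablation_run(data, variants = c("mae", "mae"),
                      config = train_config(epochs = 2, learning_rate = 1e-3,
                                            seed = 5),
                      out_csv = csv)
  expect_identical(names(tab),
                   c("variant", "psnr_mean", "psnr_sd", "ssim_mean", "ssim_sd",
                     "psnr_gain_db"))
  expect_equal(nrow(tab), 3)  # ldct baseline + two variants
  expect_identical(tab$variant[1], "ldct")
  # identical variant + identical seed: identical metrics
  expect_equal(tab[2, -1], tab[3, -1], ignore_attr = TRUE)
  expect_true(file.exists(csv))
})
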