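#' Training configuration for the reference denoiser
#'
#' Hyperparameters of the small residual convolutional denoiser used to
#' exercise the loss functions. Defaults follow the training protocol the
#' losses are designed for: Adam with `beta1 = 0.5`, `beta2 = 0.9`, initial
#' learning rate `1e-4` halved every 50 epochs, and Gaussian weight
#' initialization with standard deviation 0.01. The network itself is
#' deliberately small (a few 3x3 conv layers predicting the noise
#' residual): the loss, not the architecture, is the object of study.
#'
#' @param loss `"mae"` (per-pixel baseline), `"wp"` (weighted patch loss,
#'   which subsumes the per-pixel term), `"hf"` (the high-frequency loss
#'   added to the MAE baseline — the frequency term alone does not
#'   constrain low frequencies and is never trained stand-alone), or
#'   `"hybrid"` (`alpha1 * WP + alpha2 * HF`).
#' @param hybrid a [hybrid_config()] supplying patch/frequency parameters
#'   (used by all non-mae variants; for `"wp"`/`"hf"` only the relevant
#'   half is active).
#' @param learning_rate initial Adam learning rate.
#' @param lr_halving_interval epochs between learning-rate halvings.
#' @param epochs training epochs (>= 1).
#' @param batch_size images per gradient step.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param init_std weight initialization standard deviation.
#' @param channels,depth network width and number of conv layers.
#' @param seed master seed for initialization and data order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(loss = c("hybrid", "mae", "wp", "hf"),
                         hybrid = hybrid_config(),
                         learning_rate = 1e-4, lr_halving_interval = 50L,
                         epochs = 30L, batch_size = 1L,
                         adam_beta1 = 0.5, adam_beta2 = 0.9,
                         init_std = 0.01, channels = 16L, depth = 4L,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (epochs < 1L) stop("`epochs` must be at least 1")
  if (init_std <= 0) stop("`init_std` must be positive")
  structure(list(loss = loss, hybrid = hybrid,
                 learning_rate = as.numeric(learning_rate),
                 lr_halving_interval = as.integer(lr_halving_interval),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 init_std = as.numeric(init_std),
                 channels = as.integer(channels), depth = as.integer(depth),
                 seed = as.integer(seed)),
            class = "train_config")
}

# scalar loss + gradient wrt prediction, in the normalized domain
.loss_and_grad <- function(pred, target, config) {
  hc <- config$hybrid
  switch(config$loss,
    mae = list(loss = mean(abs(pred - target)),
               grad = sign(pred - target) / length(pred)),
    wp = list(loss = wp_loss(pred, target, hc$weight_config),
              grad = wp_loss_grad(pred, target, hc$weight_config)),
    # the high-frequency term alone is singular (every frequency inside the
    # mask is unpenalized, so low-frequency drift is free); as in the
    # ablation design it augments the per-pixel baseline
    hf = list(loss = mean(abs(pred - target)) +
                hf_loss(pred, target, r0 = hc$r0, kind = hc$filter_kind,
                        distance = hc$hf_distance),
              grad = sign(pred - target) / length(pred) +
                hf_loss_grad(pred, target, r0 = hc$r0,
                             kind = hc$filter_kind,
                             distance = hc$hf_distance)),
    hybrid = list(loss = hybrid_loss(pred, target, hc)$hybrid_loss,
                  grad = hybrid_loss_grad(pred, target, hc)))
}

#' Build an untrained reference denoiser
#'
#' Constructs the residual convolutional network with Gaussian(0,
#' `init_std^2`) kernels. At initialization the predicted noise is close to
#' zero, so the untrained model is approximately the identity.
#'
#' @param config a [train_config()].
#' @return a `denoiser_net` (internal parameter container).
#' @export
build_denoiser <- function(config = train_config()) {
  .net_init(derive_seed(config$seed, "trainer", "init"),
            init_std = config$init_std, channels = config$channels,
            depth = config$depth)
}

#' Fit the reference denoiser
#'
#' Trains the small residual CNN on paired low-dose/normal-dose images with
#' the configured loss (per-pixel MAE baseline, weighted patch loss,
#' high-frequency loss, or their hybrid). Images are standardized with
#' dataset-level mean/std computed from the training normal-dose images;
#' losses are computed in the normalized domain; patch weights and the
#' frequency mask are constants for the backward pass. Fully reproducible
#' given `config$seed`.
#'
#' @param data a dataset as returned by [load_dataset()], or any list with
#'   `train` (and optionally `val`) elements, each a list of pairs
#'   `list(ndct =, ldct =)` of `ct_image`s.
#' @param config a [train_config()].
#' @param stats optional [norm_stats()]; computed from the training NDCT
#'   images when omitted.
#' @return an object of class `ldct_denoiser` with components `net`
#'   (parameters), `config`, `stats`, and `history` (a data.frame with
#'   per-epoch `train_loss`, `val_loss`, `val_psnr`, `val_ssim`).
#' @seealso [denoise()], [ablation_run()]
#' @export
train_denoiser <- function(data, config = train_config(), stats = NULL) {
  if (is.null(data$train) || length(data$train) == 0L)
    stop("training split is empty")
  if (is.null(stats))
    stats <- compute_normalization_stats(lapply(data$train, `[[`, "ndct"))
  norm_pair <- function(p) list(x = normalize_ct(p$ldct, stats)$pixels,
                                y = normalize_ct(p$ndct, stats)$pixels)
  tr <- lapply(data$train, norm_pair)
  va <- if (!is.null(data$val) && length(data$val) > 0L)
    lapply(data$val, norm_pair) else NULL
  net <- build_denoiser(config)
  state <- .adam_init(net)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(derive_seed(config$seed, "trainer", "order"))
  hist <- data.frame(epoch = seq_len(config$epochs), lr = NA_real_,
                     train_loss = NA_real_, val_loss = NA_real_,
                     val_psnr = NA_real_, val_ssim = NA_real_)
  t_adam <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      0.5^((epoch - 1L) %/% config$lr_halving_interval)
    ord <- sample.int(length(tr))
    ep_loss <- 0
    bstart <- seq(1L, length(ord), by = config$batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
      gacc <- NULL
      for (i in idx) {
        fwd <- .net_forward(net, tr[[i]]$x, keep_cache = TRUE)
        lg <- .loss_and_grad(fwd$output, tr[[i]]$y, config)
        ep_loss <- ep_loss + lg$loss
        g <- .net_backward(net, fwd, lg$grad / length(idx))
        gacc <- if (is.null(gacc)) g else
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 gacc, g, SIMPLIFY = FALSE)
      }
      t_adam <- t_adam + 1L
      upd <- .adam_step(net, state, gacc, lr,
                        config$adam_beta1, config$adam_beta2, t_adam)
      net <- upd$net; state <- upd$state
    }
    hist$lr[epoch] <- lr
    hist$train_loss[epoch] <- ep_loss / length(tr)
    if (!is.null(va)) {
      vloss <- 0; vpsnr <- 0; vssim <- 0
      for (p in va) {
        fwd <- .net_forward(net, p$x)
        vloss <- vloss + .loss_and_grad(fwd$output, p$y, config)$loss
        dr <- diff(range(p$y))
        vpsnr <- vpsnr + psnr(fwd$output, p$y, dr)
        vssim <- vssim + ssim(fwd$output, p$y, dr)
      }
      hist$val_loss[epoch] <- vloss / length(va)
      hist$val_psnr[epoch] <- vpsnr / length(va)
      hist$val_ssim[epoch] <- vssim / length(va)
    }
  }
  structure(list(net = net, config = config, stats = stats, history = hist),
            class = "ldct_denoiser")
}

#' Denoise a low-dose image with a fitted model
#'
#' Normalizes, runs the network forward, and de-normalizes, so input and
#' output are both HU-domain images of identical shape. Deterministic.
#'
#' @param model a fitted `ldct_denoiser`.
#' @param ldct a `ct_image` in the HU domain.
#' @param stats normalization stats; defaults to the ones the model was
#'   trained with.
#' @return a `ct_image` in the HU domain.
#' @export
denoise <- function(model, ldct, stats = model$stats) {
  if (!inherits(model, "ldct_denoiser")) stop("`model` must be an ldct_denoiser")
  xn <- normalize_ct(ldct, stats)
  out <- xn
  out$pixels <- .net_forward(model$net, xn$pixels)$output
  denormalize_ct(out, stats)
}

#' @export
predict.ldct_denoiser <- function(object, newdata, ...) {
  if (is_ct_image(newdata)) return(denoise(object, newdata))
  lapply(newdata, function(im) denoise(object, im))
}

#' @export
print.ldct_denoiser <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Residual CT denoiser (%d conv layers, %d channels), loss = %s\n",
              cfg$depth, cfg$channels, cfg$loss))
  cat(sprintf("  trained %d epochs, final train loss %.6g\n",
              cfg$epochs, x$history$train_loss[cfg$epochs]))
  if (!all(is.na(x$history$val_psnr)))
    cat(sprintf("  final validation PSNR %.2f dB, SSIM %.4f\n",
                x$history$val_psnr[cfg$epochs], x$history$val_ssim[cfg$epochs]))
  invisible(x)
}

#' @export
summary.ldct_denoiser <- function(object, ...) {
  print(object)
  cat(sprintf("  normalization: mean %.2f HU, std %.2f HU\n",
              object$stats$mean, object$stats$std))
  cat(sprintf("  parameters: %d\n", length(.net_param_vector(object$net))))
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.ldct_denoiser <- function(object, ...) .net_param_vector(object$net)

#' @export
plot.ldct_denoiser <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  if (!all(is.na(h$val_psnr)))
    graphics::plot(h$epoch, h$val_psnr, type = "l", xlab = "epoch",
                   ylab = "validation PSNR (dB)", main = "PSNR", ...)
  invisible(x)
}

#' Loss-function ablation study
#'
#' Trains one model per loss variant on the same data with the same seed
#' and reports test-split image quality per variant, alongside the noisy
#' input baseline. Quality is measured in HU with each reference image's
#' own value range.
#'
#' @param data dataset as for [train_denoiser()]; must include `train` and
#'   `test` splits (and ideally `val`).
#' @param variants character vector of loss variants to compare.
#' @param config base [train_config()]; `loss` is overridden per variant.
#' @param out_csv optional path; when given the table is also written as
#'   CSV.
#' @return a data.frame with one row per variant plus a leading `ldct` row:
#'   columns `variant`, `psnr_mean`, `psnr_sd`, `ssim_mean`, `ssim_sd`,
#'   `psnr_gain_db` (mean PSNR minus the noisy-input mean PSNR).
#' @export
ablation_run <- function(data, variants = c("mae", "wp", "hf", "hybrid"),
                         config = train_config(), out_csv = NULL) {
  if (is.null(data$test) || length(data$test) == 0L)
    stop("test split is empty")
  eval_pairs <- function(preds) {
    ps <- mapply(function(pred, p) {
      dr <- diff(range(p$ndct$pixels))
      c(psnr(pred, p$ndct, dr), ssim(pred, p$ndct, dr))
    }, preds, data$test)
    c(psnr_mean = mean(ps[1, ]), psnr_sd = sd(ps[1, ]),
      ssim_mean = mean(ps[2, ]), ssim_sd = sd(ps[2, ]))
  }
  base <- eval_pairs(lapply(data$test, `[[`, "ldct"))
  rows <- list(data.frame(variant = "ldct", t(base), psnr_gain_db = 0))
  for (v in variants) {
    cfg <- config; cfg$loss <- v
    fit <- train_denoiser(data, cfg)
    preds <- lapply(data$test, function(p) denoise(fit, p$ldct))
    m <- eval_pairs(preds)
    rows <- c(rows, list(data.frame(variant = v, t(m),
                                    psnr_gain_db = m[["psnr_mean"]] - base[["psnr_mean"]])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
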