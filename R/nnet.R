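# Internal plumbing for the reference residual denoiser: a small stack of
# 3x3 "same" convolutions with ReLU between, predicting the noise residual
# (output image = input - predicted noise). Forward/backward convolutions
# live in src/conv_ops.cpp; ReLU and the optimizer are handled here.

.net_init <- function(seed, init_std = 0.01, channels = 16L, depth = 4L,
                      kernel = 3L) {
  stopifnot(depth >= 2L, kernel %% 2L == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  chans <- c(1L, rep(channels, depth - 1L), 1L)
  layers <- vector("list", depth)
  for (l in seq_len(depth)) {
    ci <- chans[l]; co <- chans[l + 1L]
    layers[[l]] <- list(
      W = array(rnorm(kernel * kernel * ci * co, 0, init_std),
                dim = c(kernel, kernel, ci, co)),
      b = rep(0, co))
  }
  structure(list(layers = layers, channels = channels, depth = depth,
                 kernel = kernel), class = "denoiser_net")
}

.net_forward <- function(net, x, keep_cache = FALSE) {
  a <- array(x, dim = c(nrow(x), ncol(x), 1L))
  cache <- if (keep_cache) vector("list", net$depth) else NULL
  for (l in seq_len(net$depth)) {
    pre <- conv2d_fwd(a, net$layers[[l]]$W, net$layers[[l]]$b)
    post <- if (l < net$depth) pmax(pre, 0) else pre
    if (keep_cache) cache[[l]] <- list(input = a, pre = pre)
    a <- post
  }
  noise <- a[, , 1L]
  list(output = x - noise, noise = noise, cache = cache)
}

# grad_output: dLoss/d(output); output = x - noise so dLoss/d(noise) = -grad
.net_backward <- function(net, fwd, grad_output) {
  g <- array(-grad_output, dim = c(nrow(grad_output), ncol(grad_output), 1L))
  grads <- vector("list", net$depth)
  for (l in rev(seq_len(net$depth))) {
    if (l < net$depth) g <- g * (fwd$cache[[l + 1L]]$input > 0)  # through ReLU
    bw <- conv2d_bwd(fwd$cache[[l]]$input, net$layers[[l]]$W, g)
    grads[[l]] <- list(W = bw$grad_weights, b = as.vector(bw$grad_bias))
    g <- bw$grad_input
  }
  grads
}

.adam_init <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
         mb = rep(0, length(ly$b)), vb = rep(0, length(ly$b))))
}

.adam_step <- function(net, state, grads, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

.net_param_vector <- function(net) {
  unlist(lapply(net$layers, function(ly) c(as.vector(ly$W), ly$b)))
}
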