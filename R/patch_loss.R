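#' Weight configuration for the patch loss
#'
#' Controls how an image pair is cut into non-overlapping patches and how
#' per-patch weights are formed. Weights are each patch's mean absolute
#' error divided by a reference statistic (the median of the per-patch MAEs)
#' and then clamped to `[w_min, w_max]`. The clamp prevents a single
#' hard-to-denoise region from dominating the update; `[0.25, 4]` is the
#' default operating range.
#'
#' @param grid_rows,grid_cols patch grid shape; image dimensions must be
#'   exactly divisible by them. Default 4 x 4 (N = 16 patches).
#' @param w_min,w_max clamp bounds, `0 < w_min <= 1 <= w_max`.
#' @return an object of class `weight_config`.
#' @export
weight_config <- function(grid_rows = 4, grid_cols = 4, w_min = 0.25, w_max = 4) {
  if (grid_rows < 1 || grid_cols < 1 || grid_rows != round(grid_rows) ||
      grid_cols != round(grid_cols))
    stop("grid_rows and grid_cols must be positive integers")
  if (!(w_min > 0 && w_min <= 1 && w_max >= 1))
    stop("weight clamp must satisfy 0 < w_min <= 1 <= w_max, got [",
         w_min, ", ", w_max, "]")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 w_min = as.numeric(w_min), w_max = as.numeric(w_max),
                 reference_stat = "MEDIAN"),
            class = "weight_config")
}

.as_pixels <- function(x) if (is_ct_image(x)) x$pixels else as.matrix(x)

.patch_bounds <- function(n, parts) {
  if (n %% parts != 0L)
    stop("image dimension ", n, " is not divisible by patch grid size ", parts,
         " (no silent trimming)")
  size <- n %/% parts
  lapply(seq_len(parts), function(i) ((i - 1L) * size + 1L):(i * size))
}

#' Partition an image pair into aligned patches
#'
#' Splits both images into a `grid_rows x grid_cols` grid of non-overlapping
#' rectangular patches that tile each image exactly once. Patches are
#' returned in row-major order (left to right, then top to bottom).
#'
#' @param generated,target matrices or `ct_image`s of identical shape.
#' @param config a [weight_config()].
#' @return a list of `N = grid_rows * grid_cols` elements, each a list with
#'   matrices `generated` and `target` plus the patch's `row`/`col` grid
#'   position.
#' @export
partition_patches <- function(generated, target, config = weight_config()) {
  g <- .as_pixels(generated); t <- .as_pixels(target)
  if (!identical(dim(g), dim(t)))
    stop("generated and target must have the same shape")
  rb <- .patch_bounds(nrow(g), config$grid_rows)
  cb <- .patch_bounds(ncol(g), config$grid_cols)
  out <- vector("list", config$grid_rows * config$grid_cols)
  k <- 1L
  for (i in seq_len(config$grid_rows)) {
    for (j in seq_len(config$grid_cols)) {
      out[[k]] <- list(generated = g[rb[[i]], cb[[j]], drop = FALSE],
                       target = t[rb[[i]], cb[[j]], drop = FALSE],
                       row = i, col = j)
      k <- k + 1L
    }
  }
  out
}

#' Median-normalized clamped patch weights
#'
#' Given per-patch losses `l_i`, the weight of patch `i` is
#' `w_i = l_i / I` with `I = median(l)` (even-length medians average the two
#' central values), clamped to `[w_min, w_max]`. If the median is zero
#' (identical images) all weights are 1 by convention. Weights are treated
#' as constants during gradient computation: no derivative flows through
#' them.
#'
#' @param patch_losses numeric vector (length >= 2) of non-negative
#'   per-patch losses.
#' @param config a [weight_config()].
#' @return numeric weight vector of the same length.
#' @export
compute_patch_weights <- function(patch_losses, config = weight_config()) {
  if (length(patch_losses) < 2L)
    stop("need at least 2 patch losses")
  if (any(!is.finite(patch_losses)) || any(patch_losses < 0))
    stop("patch losses must be finite and non-negative")
  I <- median(patch_losses)
  w <- if (I == 0) rep(1, length(patch_losses)) else patch_losses / I
  pmin(pmax(w, config$w_min), config$w_max)
}

#' Weighted patch loss (WPLoss)
#'
#' The adaptive region-weighted reconstruction loss: the image pair is
#' partitioned into patches, each patch's mean absolute error is computed,
#' and the per-patch MAEs are summed with median-normalized clamped weights
#' (see [compute_patch_weights()]). Regions where the denoiser currently
#' does badly (large patch MAE relative to the median patch) receive
#' proportionally more weight, regions that are already well reconstructed
#' are down-weighted, so optimization effort tracks local denoising
#' difficulty.
#'
#' @inheritParams partition_patches
#' @param detail if `TRUE` return a list with the scalar and a per-patch
#'   diagnostic `patch_grid`; otherwise just the scalar.
#' @return scalar loss, or a list with elements `loss` and `patch_grid`
#'   (a data.frame with per-patch row/col, MAE and weight).
#' @export
wp_loss <- function(generated, target, config = weight_config(), detail = FALSE) {
  patches <- partition_patches(generated, target, config)
  maes <- vapply(patches, function(p) mean(abs(p$generated - p$target)), 0.0)
  w <- compute_patch_weights(maes, config)
  loss <- sum(w * maes)
  if (!detail) return(loss)
  grid <- data.frame(row = vapply(patches, `[[`, 0L, "row"),
                     col = vapply(patches, `[[`, 0L, "col"),
                     patch_mae = maes, weight = w)
  list(loss = loss, patch_grid = grid)
}

#' Gradient of WPLoss with respect to the generated image
#'
#' The patch weights are constants for gradient purposes, so within patch
#' `i` the gradient of `w_i * MAE_i` is `w_i * sign(g - t) / n_i` with
#' `n_i` the patch pixel count. Ties (`g == t`) take subgradient 0.
#'
#' @inheritParams wp_loss
#' @return a matrix of the same shape as the inputs.
#' @export
wp_loss_grad <- function(generated, target, config = weight_config()) {
  g <- .as_pixels(generated); t <- .as_pixels(target)
  if (!identical(dim(g), dim(t)))
    stop("generated and target must have the same shape")
  rb <- .patch_bounds(nrow(g), config$grid_rows)
  cb <- .patch_bounds(ncol(g), config$grid_cols)
  maes <- numeric(config$grid_rows * config$grid_cols)
  k <- 1L
  for (i in seq_len(config$grid_rows)) for (j in seq_len(config$grid_cols)) {
    maes[k] <- mean(abs(g[rb[[i]], cb[[j]]] - t[rb[[i]], cb[[j]]]))
    k <- k + 1L
  }
  w <- compute_patch_weights(maes, config)
  grad <- matrix(0, nrow(g), ncol(g))
  npix <- (nrow(g) %/% config$grid_rows) * (ncol(g) %/% config$grid_cols)
  k <- 1L
  for (i in seq_len(config$grid_rows)) for (j in seq_len(config$grid_cols)) {
    d <- g[rb[[i]], cb[[j]]] - t[rb[[i]], cb[[j]]]
    grad[rb[[i]], cb[[j]]] <- w[k] * sign(d) / npix
    k <- k + 1L
  }
  grad
}
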