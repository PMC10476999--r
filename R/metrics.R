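#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical images have zero MSE
#' and return `Inf` as a sentinel. The default `data_range` is the value
#' range `max - min` of the reference image `y`; fixed CT-style ranges
#' (e.g. 4095 for 12-bit HU data, 255 for 8-bit display data) can be passed
#' explicitly.
#'
#' @param x,y matrices or `ct_image`s of identical shape; `y` is the
#'   reference.
#' @param data_range positive dynamic range used for the peak.
#' @return scalar PSNR in dB.
#' @export
psnr <- function(x, y, data_range = NULL) {
  xp <- .as_pixels(x); yp <- .as_pixels(y)
  if (!identical(dim(xp), dim(yp)))
    stop("images must have the same shape")
  if (is.null(data_range)) data_range <- diff(range(yp))
  if (!is.numeric(data_range) || data_range <= 0)
    stop("`data_range` must be positive")
  mse <- mean((xp - yp)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

.gauss_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable "valid" 2-D convolution with a symmetric 1-D kernel
.conv2_valid <- function(x, k) {
  n <- length(k); m <- nrow(x); p <- ncol(x)
  rows <- m - n + 1L; cols <- p - n + 1L
  tmp <- matrix(0, rows, p)
  for (i in seq_len(n)) tmp <- tmp + k[i] * x[i:(i + rows - 1L), , drop = FALSE]
  out <- matrix(0, rows, cols)
  for (j in seq_len(n)) out <- out + k[j] * tmp[, j:(j + cols - 1L), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11 x 11 Gaussian window
#' (sigma = 1.5) and stabilizers `C1 = (K1 * data_range)^2`,
#' `C2 = (K2 * data_range)^2`. Local statistics are computed over all fully
#' interior window positions. Symmetric in its arguments and exactly 1 for
#' identical images.
#'
#' @inheritParams psnr
#' @param window_size odd Gaussian window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 stabilizer fractions of the dynamic range (defaults 0.01,
#'   0.03).
#' @return scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = NULL, window_size = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  xp <- .as_pixels(x); yp <- .as_pixels(y)
  if (!identical(dim(xp), dim(yp)))
    stop("images must have the same shape")
  if (min(dim(xp)) < window_size)
    stop("image min dimension ", min(dim(xp)), " is smaller than the SSIM window (",
         window_size, ")")
  if (is.null(data_range)) data_range <- diff(range(yp))
  if (!is.numeric(data_range) || data_range <= 0)
    stop("`data_range` must be positive")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  k <- .gauss_kernel_1d(window_size, sigma)
  mu_x <- .conv2_valid(xp, k); mu_y <- .conv2_valid(yp, k)
  sxx <- .conv2_valid(xp * xp, k) - mu_x^2
  syy <- .conv2_valid(yp * yp, k) - mu_y^2
  sxy <- .conv2_valid(xp * yp, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' PSNR/SSIM over rectangular regions of interest
#'
#' Computes PSNR and SSIM on cropped sub-images, one result per ROI, in
#' input order. ROIs are 0-based, half-open rectangles
#' `(row0, col0, height, width)`, matching how regions are typically marked
#' on evaluation figures.
#'
#' @inheritParams psnr
#' @param rois list of ROIs, each a numeric vector or list with elements
#'   `row0`, `col0`, `height`, `width`.
#' @return a data.frame with one row per ROI: `roi`, `row0`, `col0`,
#'   `height`, `width`, `psnr`, `ssim`.
#' @export
roi_metrics <- function(x, y, rois, data_range = NULL) {
  xp <- .as_pixels(x); yp <- .as_pixels(y)
  if (!identical(dim(xp), dim(yp)))
    stop("images must have the same shape")
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    r <- as.numeric(unlist(rois[[i]]))
    if (length(r) != 4L) stop("ROI ", i, " must have 4 elements")
    r0 <- r[1]; c0 <- r[2]; h <- r[3]; w <- r[4]
    if (r0 < 0 || c0 < 0 || h < 1 || w < 1 ||
        r0 + h > nrow(xp) || c0 + w > ncol(xp))
      stop("ROI ", i, " is out of image bounds")
    rs <- (r0 + 1):(r0 + h); cs <- (c0 + 1):(c0 + w)
    xs <- xp[rs, cs, drop = FALSE]; ys <- yp[rs, cs, drop = FALSE]
    dr <- if (is.null(data_range)) diff(range(ys)) else data_range
    out[[i]] <- data.frame(roi = i, row0 = r0, col0 = c0, height = h, width = w,
                           psnr = psnr(xs, ys, dr), ssim = ssim(xs, ys, dr))
  }
  do.call(rbind, out)
}
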