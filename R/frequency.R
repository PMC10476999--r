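#' 2-D discrete Fourier transform and inverse
#'
#' `dft2()` computes `F(u, v) = sum_{x,y} f(x, y) exp(-2 pi i (u x / m + v y / n))`
#' for an `m x n` input; `idft2()` applies the inverse with the `1/(m n)`
#' normalization so that `idft2(dft2(f)) == f` to roundoff. Thin wrappers
#' over [stats::fft()] that pin down the sign and normalization convention
#' used throughout the frequency-loss code.
#'
#' @param x real (or complex) matrix for `dft2`; complex matrix for `idft2`.
#' @return complex matrix of the same shape (`idft2` returns complex; take
#'   `Re()` for real inputs).
#' @export
dft2 <- function(x) {
  x <- .as_pixels_cplx(x)
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop("non-finite values in DFT input")
  stats::fft(x)
}

#' @rdname dft2
#' @export
idft2 <- function(x) {
  x <- .as_pixels_cplx(x)
  stats::fft(x, inverse = TRUE) / length(x)
}

.as_pixels_cplx <- function(x) {
  if (is_ct_image(x)) x <- x$pixels
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

.centered_index <- function(n) {
  # signed centered DFT index for bins 0..n-1; even n puts Nyquist at -n/2
  i <- 0:(n - 1L)
  ((i + n %/% 2L) %% n) - n %/% 2L
}

#' High-pass frequency mask
#'
#' Builds the per-bin multiplier grid `G` applied to a centered 2-D DFT to
#' keep only high spatial frequencies. The normalized radius of bin
#' `(u, v)` is `rho = sqrt((u'/m)^2 + (v'/n)^2)` where `u'`, `v'` are the
#' signed centered indices (for even dimensions the unmatched Nyquist bin
#' sits at `-m/2`). Two filter families:
#'
#' * `"ideal"` — binary: 0 where `rho <= r0`, 1 elsewhere.
#' * `"gaussian"` — smooth: `1 - exp(-rho^2 / (2 r0^2))`.
#'
#' The DC bin is always zeroed (for any `r0 >= 0`), so filtered images of
#' mean-shifted inputs are identical. The mask is symmetric under frequency
#' negation modulo the grid size, which guarantees that filtering a real
#' image returns a real image up to roundoff. The largest radius present on
#' any grid is `sqrt(0.5) ~ 0.707`; `r0` at or above that zeroes every bin.
#'
#' @param shape integer vector `c(m, n)`.
#' @param r0 cutoff as a fraction of the sampling rate, in `[0, 1]`.
#'   Typical values lie in `[0, 0.5]` (the per-axis Nyquist fraction).
#' @param kind `"ideal"` or `"gaussian"`.
#' @return an object of class `frequency_mask` with fields `mask`, `r0`,
#'   `kind`.
#' @export
make_highpass_mask <- function(shape, r0 = 0.1, kind = c("ideal", "gaussian")) {
  kind <- match.arg(kind)
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 < 0 || r0 > 1)
    stop("`r0` must be in [0, 1], got ", r0)
  m <- as.integer(shape[1]); n <- as.integer(shape[2])
  if (m < 1L || n < 1L) stop("invalid mask shape")
  u <- .centered_index(m) / m
  v <- .centered_index(n) / n
  rho <- sqrt(outer(u^2, v^2, `+`))
  mask <- if (kind == "ideal") {
    ifelse(rho <= r0, 0, 1)
  } else if (r0 == 0) {
    ifelse(rho == 0, 0, 1)
  } else {
    1 - exp(-rho^2 / (2 * r0^2))
  }
  mask[1L, 1L] <- 0  # DC always removed
  structure(list(mask = mask, r0 = r0, kind = kind), class = "frequency_mask")
}

#' @export
print.frequency_mask <- function(x, ...) {
  cat(sprintf("<frequency_mask %d x %d, kind=%s, r0=%g, %d of %d bins passed>\n",
              nrow(x$mask), ncol(x$mask), x$kind, x$r0,
              sum(x$mask > 0), length(x$mask)))
  invisible(x)
}

.mask_grid <- function(mask, shape) {
  m <- if (inherits(mask, "frequency_mask")) mask$mask else as.matrix(mask)
  if (!identical(dim(m), as.integer(shape)))
    stop("frequency mask shape ", paste(dim(m), collapse = "x"),
         " does not match image shape ", paste(shape, collapse = "x"))
  m
}

#' Extract the high-frequency part of an image
#'
#' Transforms to the frequency domain, multiplies by the high-pass mask,
#' and transforms back, returning the real part. For a symmetric mask on a
#' real input the imaginary residual is pure roundoff. With the DC bin
#' zeroed the output has (numerically) zero mean.
#'
#' @param image matrix or `ct_image`.
#' @param mask a [make_highpass_mask()] result (or bare matrix) matching the
#'   image shape.
#' @return a plain matrix (the filtered image).
#' @export
highpass_image <- function(image, mask) {
  x <- .as_pixels(image)
  g <- .mask_grid(mask, dim(x))
  Re(idft2(g * dft2(x)))
}

#' High-frequency loss (HFLoss)
#'
#' Mean absolute difference between the high-pass filtered generated and
#' target images. Texture and edge content lives in the high-frequency part
#' of the spectrum, so this term penalizes exactly the detail that plain
#' per-pixel losses let a denoiser smooth away. It is non-negative,
#' symmetric in its arguments, and exactly zero when the two images differ
#' only by a constant offset (a pure DC difference). An L2 variant
#' (`distance = "l2"`, mean squared difference) is available but L1 is the
#' default.
#'
#' @param generated,target matrices or `ct_image`s of identical shape.
#' @param mask a [make_highpass_mask()] for that shape; built on the fly
#'   from `r0`/`kind` when omitted.
#' @param r0,kind passed to [make_highpass_mask()] when `mask` is `NULL`.
#' @param distance `"l1"` (default) or `"l2"`.
#' @return scalar loss.
#' @export
hf_loss <- function(generated, target, mask = NULL, r0 = 0.1,
                    kind = "ideal", distance = c("l1", "l2")) {
  distance <- match.arg(distance)
  g <- .as_pixels(generated); t <- .as_pixels(target)
  if (!identical(dim(g), dim(t)))
    stop("generated and target must have the same shape")
  if (is.null(mask)) mask <- make_highpass_mask(dim(g), r0 = r0, kind = kind)
  d <- highpass_image(g - t, mask)  # linearity: H(g) - H(t) = H(g - t)
  if (distance == "l1") mean(abs(d)) else mean(d^2)
}

#' Gradient of HFLoss with respect to the generated image
#'
#' The high-pass operator `H` is a circular convolution with a real, even
#' kernel (the mask is symmetric under frequency negation), hence
#' self-adjoint; the gradient of `mean(|H(g - t)|)` is therefore
#' `H(sign(H(g - t))) / (m n)` (and `2 H(H(g - t)) / (m n)` for L2).
#'
#' @inheritParams hf_loss
#' @return a matrix of the same shape as the inputs.
#' @export
hf_loss_grad <- function(generated, target, mask = NULL, r0 = 0.1,
                         kind = "ideal", distance = c("l1", "l2")) {
  distance <- match.arg(distance)
  g <- .as_pixels(generated); t <- .as_pixels(target)
  if (!identical(dim(g), dim(t)))
    stop("generated and target must have the same shape")
  if (is.null(mask)) mask <- make_highpass_mask(dim(g), r0 = r0, kind = kind)
  d <- highpass_image(g - t, mask)
  if (distance == "l1") highpass_image(sign(d), mask) / length(d)
  else 2 * highpass_image(d, mask) / length(d)
}
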