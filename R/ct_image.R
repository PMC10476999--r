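#' CT image container
#'
#' A `ct_image` is a 2-D real-valued matrix tagged with the value domain its
#' pixels live in and the in-plane pixel spacing. The domain tag keeps unit
#' bookkeeping honest across the pipeline: Hounsfield units (`"HU"`,
#' water = 0, air = -1000), affinely standardized training units
#' (`"NORMALIZED"`), linear attenuation coefficients in 1/mm
#' (`"ATTENUATION"`), and photon counts (`"COUNTS"`).
#'
#' Images must be at least 8 x 8 (the minimum that supports patch grids and
#' SSIM windows) and contain only finite values.
#'
#' @param pixels numeric matrix of pixel values.
#' @param domain one of `"HU"`, `"NORMALIZED"`, `"ATTENUATION"`, `"COUNTS"`.
#' @param pixel_spacing positive pixel spacing in mm (metadata only).
#' @return an object of class `ct_image`.
#' @export
ct_image <- function(pixels, domain = "HU", pixel_spacing = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("image must be at least 8 x 8, got ", nrow(pixels), " x ", ncol(pixels))
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values")
  domain <- match.arg(domain, .domain_levels)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L || pixel_spacing <= 0)
    stop("`pixel_spacing` must be a positive scalar")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, domain = domain,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image %d x %d, domain=%s, spacing=%g mm, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$domain, x$pixel_spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

#' @rdname ct_image
#' @param x object to test or coerce.
#' @export
is_ct_image <- function(x) inherits(x, "ct_image")

#' @rdname ct_image
#' @param ... passed to [ct_image()] when coercing a bare matrix.
#' @export
as_ct_image <- function(x, ...) {
  if (is_ct_image(x)) x else ct_image(as.matrix(x), ...)
}

.assert_domain <- function(image, domain, arg = "image") {
  if (!is_ct_image(image)) stop("`", arg, "` must be a ct_image")
  if (image$domain != domain)
    stop("`", arg, "` must be in the ", domain, " domain, got ", image$domain)
  invisible(image)
}

.assert_same_shape <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("images must have the same shape: ",
         paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"))
  invisible(NULL)
}

#' Normalization statistics
#'
#' Mean and standard deviation used for the affine standardization applied
#' before training. Stats are typically computed once over the full set of
#' normal-dose images (so the HU scale stays consistent across image pairs);
#' a per-image mode is available via `per_image = TRUE` in
#' [compute_normalization_stats()].
#'
#' @param mean pixel mean (HU).
#' @param std positive pixel standard deviation (HU).
#' @return an object of class `norm_stats`.
#' @export
norm_stats <- function(mean, std) {
  if (!is.numeric(std) || length(std) != 1L || !is.finite(std) || std <= 0)
    stop("`std` must be a positive finite scalar")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("`mean` must be a finite scalar")
  structure(list(mean = as.numeric(mean), std = as.numeric(std)),
            class = "norm_stats")
}

#' @rdname norm_stats
#' @param images a `ct_image` or list of `ct_image`s (HU domain).
#' @param per_image if `TRUE`, return a list of per-image stats instead of
#'   one pooled set.
#' @export
compute_normalization_stats <- function(images, per_image = FALSE) {
  if (is_ct_image(images)) images <- list(images)
  if (per_image)
    return(lapply(images, function(im) norm_stats(mean(im$pixels), sd(im$pixels))))
  v <- unlist(lapply(images, function(im) as.vector(im$pixels)))
  norm_stats(mean(v), sd(v))
}

#' Standardize / de-standardize CT images for training
#'
#' `normalize_ct()` maps an HU image to training units via
#' `(pixels - mean) / std`; `denormalize_ct()` is its exact affine inverse.
#' No clipping is applied: normalization is affine, and values outside
#' `[-1, 1]` are legitimate.
#'
#' @param image a `ct_image` (HU domain for `normalize_ct`, NORMALIZED for
#'   `denormalize_ct`).
#' @param stats a [norm_stats()] object.
#' @return a `ct_image` in the complementary domain.
#' @export
normalize_ct <- function(image, stats) {
  .assert_domain(image, "HU")
  if (!inherits(stats, "norm_stats")) stop("`stats` must be a norm_stats object")
  out <- image
  out$pixels <- (image$pixels - stats$mean) / stats$std
  out$domain <- "NORMALIZED"
  out
}

#' @rdname normalize_ct
#' @export
denormalize_ct <- function(image, stats) {
  .assert_domain(image, "NORMALIZED")
  if (!inherits(stats, "norm_stats")) stop("`stats` must be a norm_stats object")
  out <- image
  out$pixels <- image$pixels * stats$std + stats$mean
  out$domain <- "HU"
  out
}

#' Apply a display window for visualization
#'
#' Linearly maps the HU interval `[low, high]` to `[0, 1]`, clipping outside.
#' The window is stored as explicit low/high bounds (e.g. an abdominal
#' soft-tissue window of `[-160, 240]` HU, i.e. center 40 / width 400) to
#' avoid center-versus-width ambiguity. Used only for report figures, never
#' inside losses or metrics.
#'
#' @param image a `ct_image` in the HU domain.
#' @param low,high window bounds in HU, `high > low`.
#' @return a `ct_image` (NORMALIZED domain) with values in `[0, 1]`.
#' @export
apply_display_window <- function(image, low = -160, high = 240) {
  .assert_domain(image, "HU")
  if (!is.numeric(low) || !is.numeric(high) || high <= low)
    stop("display window must satisfy high > low (width > 0)")
  out <- image
  out$pixels <- pmin(pmax((image$pixels - low) / (high - low), 0), 1)
  out$domain <- "NORMALIZED"
  out
}
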