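#' Read and write CT images
#'
#' Two on-disk formats are supported:
#'
#' * `"array"` — the package's lossless reference container: a small
#'   self-describing binary file (magic header, dimensions, domain tag,
#'   pixel spacing, little-endian float64 pixels in column-major order).
#'   Round trips are bit-identical.
#' * `"tiff16"` — 16-bit grayscale TIFF for interchange with image viewers.
#'   Stored value is `round(HU + 1024)` clipped to `[0, 65535]`, so the
#'   round trip is exact to the 1 HU quantization step for HU in
#'   `[-1024, 64511]`. Only HU-domain images can be written in this format.
#'
#' @param path file path.
#' @param format `"array"` or `"tiff16"`. `read_ct_image` infers the format
#'   from the extension (`.tif`/`.tiff` vs anything else) when not given.
#' @param image a `ct_image`.
#' @param pixel_spacing spacing to attach when reading formats that do not
#'   store it (tiff16).
#' @return `read_ct_image` returns a `ct_image`; `write_ct_image` returns
#'   `path` invisibly.
#' @export
write_ct_image <- function(image, path, format = c("array", "tiff16")) {
  format <- match.arg(format)
  if (!is_ct_image(image)) stop("`image` must be a ct_image")
  if (format == "array") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("CTARR01\n"), con)
    writeBin(c(nrow(image$pixels), ncol(image$pixels),
               match(image$domain, .domain_levels)), con,
             size = 4L, endian = "little")
    writeBin(image$pixel_spacing, con, size = 8L, endian = "little")
    writeBin(as.vector(image$pixels), con, size = 8L, endian = "little")
  } else {
    .assert_domain(image, "HU")
    stored <- pmin(pmax(round(image$pixels + 1024), 0), 65535)
    tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(path, format = NULL, pixel_spacing = 1) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff16" else "array"
  format <- match.arg(format, c("array", "tiff16"))
  if (format == "array") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", 8L))
    if (!identical(magic, "CTARR01\n"))
      stop("not a CT array container (bad magic): ", path)
    hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    spacing <- readBin(con, "double", 1L, size = 8L, endian = "little")
    px <- readBin(con, "double", hdr[1] * hdr[2], size = 8L, endian = "little")
    if (length(px) != hdr[1] * hdr[2])
      stop("truncated CT array container: ", path)
    if (any(!is.finite(px))) stop("non-finite pixels in: ", path)
    if (hdr[1] < 8L || hdr[2] < 8L)
      stop("image in ", path, " is below the 8 x 8 minimum size")
    ct_image(matrix(px, hdr[1], hdr[2]), domain = .domain_levels[hdr[3]],
             pixel_spacing = spacing)
  } else {
    stored <- tiff::readTIFF(path)
    if (length(dim(stored)) == 3L) stored <- stored[, , 1L]
    if (nrow(stored) < 8L || ncol(stored) < 8L)
      stop("image in ", path, " is below the 8 x 8 minimum size")
    ct_image(stored * 65535 - 1024, domain = "HU", pixel_spacing = pixel_spacing)
  }
}
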