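#' Synthetic CT phantom specification
#'
#' Parameters of the deterministic abdomen-like test phantom: an elliptical
#' body on an air background, filled with soft tissue, with a fat layer, a
#' liver-like region carrying band-limited texture, randomly placed
#' high-attenuation bone-like ellipses, and one low-contrast lesion inside
#' the liver. HU palette (fixed constants): air -1000, fat -90, soft
#' tissue 40, liver 55, lesion 55 + `lesion_contrast`, bone 700.
#'
#' @param size square image side in pixels (default 224; must be >= 32 and
#'   divisible by 4 so the default patch grid tiles exactly).
#' @param n_ellipses number of extra random soft-tissue ellipses.
#' @param n_bones number of bone-like high-attenuation ellipses (>= 1).
#' @param lesion_contrast lesion HU offset from liver; |contrast| <= 50
#'   keeps it low-contrast.
#' @param texture_amplitude HU standard deviation of the liver texture
#'   (0 disables texture).
#' @param texture_correlation_length correlation length of the texture in
#'   pixels.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 224L, n_ellipses = 3L, n_bones = 2L,
                         lesion_contrast = -20, texture_amplitude = 12,
                         texture_correlation_length = 4, seed = 1L) {
  if (size < 32L) stop("phantom size must be at least 32")
  if (size %% 4L != 0L) stop("phantom size must be divisible by 4")
  if (abs(lesion_contrast) > 50)
    stop("|lesion_contrast| must be <= 50 HU (low-contrast by construction)")
  if (n_bones < 1L) stop("need at least one bone-like structure")
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 n_bones = as.integer(n_bones),
                 lesion_contrast = as.numeric(lesion_contrast),
                 texture_amplitude = as.numeric(texture_amplitude),
                 texture_correlation_length = as.numeric(texture_correlation_length),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# inside-ellipse mask over the pixel grid; center/axes in [0,1] image units
.ellipse_mask <- function(size, cx, cy, rx, ry, angle = 0) {
  xs <- (seq_len(size) - 0.5) / size
  X <- matrix(rep(xs, each = size), size, size)
  Y <- matrix(rep(xs, times = size), size, size)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# band-limited correlated noise field via frequency-domain Gaussian shaping
.textured_field <- function(size, amplitude, corr_len) {
  white <- matrix(rnorm(size * size), size, size)
  u <- .centered_index(size) / size
  rho <- sqrt(outer(u^2, u^2, `+`))
  shape <- exp(-(rho * corr_len)^2)
  f <- Re(idft2(dft2(white) * shape))
  f <- f - mean(f)
  if (sd(f) > 0) f <- f / sd(f)
  amplitude * f
}

#' Generate a synthetic CT phantom
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' same seed, bit-identical image. Output spans the full CT range (air
#' around -1000 HU, soft tissue around 0-100 HU, bone above 300 HU) and is
#' clipped to `[-1000, 2000]` HU.
#'
#' @param spec a [phantom_spec()].
#' @return a `ct_image` in the HU domain.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)
  s <- spec$size
  img <- matrix(-1000, s, s)                                   # air
  body <- .ellipse_mask(s, 0.5, 0.5, 0.40, 0.33)
  img[body] <- -90                                             # fat layer
  soft <- .ellipse_mask(s, 0.5, 0.5, 0.36, 0.29)
  img[soft] <- 40                                              # soft tissue
  for (k in seq_len(spec$n_ellipses)) {                        # organ-ish blobs
    m <- .ellipse_mask(s, runif(1, 0.3, 0.7), runif(1, 0.35, 0.65),
                       runif(1, 0.04, 0.10), runif(1, 0.03, 0.08),
                       runif(1, 0, pi))
    img[m & soft] <- runif(1, 20, 80)
  }
  liver <- .ellipse_mask(s, 0.36, 0.42, 0.14, 0.11, 0.3)       # textured region
  img[liver & soft] <- 55
  if (spec$texture_amplitude > 0) {
    tex <- .textured_field(s, spec$texture_amplitude,
                           spec$texture_correlation_length)
    img[liver & soft] <- img[liver & soft] + tex[liver & soft]
  }
  lesion <- .ellipse_mask(s, 0.38, 0.44, 0.030, 0.025)         # low-contrast lesion
  img[lesion & soft] <- 55 + spec$lesion_contrast
  for (k in seq_len(spec$n_bones)) {                           # bone-like structures
    cx <- runif(1, 0.40, 0.60); cy <- runif(1, 0.62, 0.72)
    m <- .ellipse_mask(s, cx, cy, runif(1, 0.025, 0.045),
                       runif(1, 0.02, 0.035), runif(1, 0, pi))
    img[m & body] <- 700
  }
  img <- pmin(pmax(img, -1000), 2000)
  ct_image(img, domain = "HU", pixel_spacing = 1)
}

#' Generate a paired NDCT/LDCT dataset
#'
#' Renders `n` phantoms (seeds derived from `master_seed`), simulates the
#' paired low-dose image for each at the configured dose, writes both to
#' `out_dir` in the lossless array container, assigns train/validation/test
#' splits in a fixed 6:2:2 pattern (exact when `n` is divisible by 5), and
#' writes a JSON manifest from which the whole dataset can be regenerated
#' bit-identically.
#'
#' @param n number of image pairs.
#' @param out_dir output directory (created if missing).
#' @param spec template [phantom_spec()]; the per-image seed is overridden.
#' @param dose a [dose_model()]; the per-image noise seed is derived from
#'   `master_seed` as well.
#' @param master_seed root seed for the whole dataset.
#' @param mode `"projection"` for the full Radon/FBP simulator or
#'   `"image"` for fast direct noise insertion.
#' @param n_angles projection angles for projection mode.
#' @return the manifest as a list (also written to
#'   `file.path(out_dir, "manifest.json")`); entries carry `id`, seeds,
#'   file names, and `split`.
#' @export
generate_dataset <- function(n, out_dir, spec = phantom_spec(),
                             dose = dose_model(dose_fraction = 0.25),
                             master_seed = 1L,
                             mode = c("projection", "image"),
                             n_angles = 180L) {
  mode <- match.arg(mode)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  split_pattern <- c("train", "train", "train", "val", "test")  # 6:2:2 over blocks of 5
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- derive_seed(master_seed, "phantom", i)
    nseed <- derive_seed(master_seed, "noise", i)
    sp <- spec; sp$seed <- pseed
    nd <- generate_phantom(sp)
    dm <- dose; dm$seed <- nseed
    ld <- if (mode == "projection") simulate_ldct(nd, dm, n_angles = n_angles)
          else inject_image_noise(nd, dm)
    nd_file <- sprintf("ndct_%03d.ctarr", i)
    ld_file <- sprintf("ldct_%03d.ctarr", i)
    write_ct_image(nd, file.path(out_dir, nd_file))
    write_ct_image(ld, file.path(out_dir, ld_file))
    blk <- ((i - 1L) %% 5L)
    split <- if (blk < 3L) "train" else if (blk == 3L) "val" else "test"
    entries[[i]] <- list(id = i, ndct = nd_file, ldct = ld_file,
                         phantom_seed = pseed, noise_seed = nseed, split = split)
  }
  manifest <- list(n = n, master_seed = master_seed, mode = mode,
                   n_angles = n_angles,
                   dose = dose[c("N0", "dose_fraction", "K")],
                   phantom = unclass(spec)[setdiff(names(unclass(spec)), "seed")],
                   entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a generated dataset from its manifest
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a list with `train`, `val`, `test`: each a list of pairs
#'   `list(ndct = ct_image, ldct = ct_image)`, plus the parsed `manifest`.
#' @export
load_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list(train = list(), val = list(), test = list(), manifest = mf)
  for (e in mf$entries) {
    pair <- list(ndct = read_ct_image(file.path(dir, e$ndct)),
                 ldct = read_ct_image(file.path(dir, e$ldct)))
    out[[e$split]] <- c(out[[e$split]], list(pair))
  }
  out
}
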