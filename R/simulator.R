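#' Dose model for quantum-noise simulation
#'
#' Parameters of the photon-counting noise model. A measurement along ray
#' `i` with line integral `p_i` yields detected counts
#' `c_i = K * Poisson(N0_eff * exp(-p_i))` where
#' `N0_eff = N0 * dose_fraction` is the incident photon intensity after
#' dose reduction (Beer-Lambert attenuation of the incident flux). A
#' quarter-dose acquisition is `dose_fraction = 0.25`.
#'
#' @param N0 incident photon intensity per detector bin at full dose.
#' @param dose_fraction dose level in `(0, 1]`; multiplies `N0`.
#' @param K photon-to-electron conversion gain (default 1: pure counting).
#' @param seed integer RNG seed for reproducible noise draws.
#' @return an object of class `dose_model`.
#' @export
dose_model <- function(N0 = 1e5, dose_fraction = 1, K = 1, seed = 1L) {
  if (!is.numeric(N0) || N0 <= 0) stop("`N0` must be positive")
  if (!is.numeric(K) || K <= 0) stop("`K` must be positive")
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("`dose_fraction` must be in (0, 1]")
  structure(list(N0 = as.numeric(N0), dose_fraction = as.numeric(dose_fraction),
                 K = as.numeric(K), seed = as.integer(seed)),
            class = "dose_model")
}

#' Sinogram container
#'
#' Projection-domain grid: one row per projection angle, one column per
#' detector bin. `domain` is `"LINE_INTEGRAL"` (dimensionless optical
#' depth) or `"COUNTS"` (photon counts).
#'
#' @param values numeric `n_angles x n_detectors` matrix.
#' @param angles projection angles in radians, in `[0, pi)`.
#' @param detector_spacing detector bin spacing in mm.
#' @param domain `"LINE_INTEGRAL"` or `"COUNTS"`.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, angles, detector_spacing = 1,
                     domain = c("LINE_INTEGRAL", "COUNTS")) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (nrow(values) != length(angles))
    stop("number of sinogram rows must equal number of angles")
  if (domain == "LINE_INTEGRAL" && any(values < -1e-9))
    stop("line integrals must be non-negative")
  if (domain == "COUNTS" && any(values < 0))
    stop("counts must be non-negative")
  structure(list(values = values, angles = as.numeric(angles),
                 detector_spacing = as.numeric(detector_spacing),
                 domain = domain),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d angles x %d detectors, domain=%s>\n",
              nrow(x$values), ncol(x$values), x$domain))
  invisible(x)
}

#' Convert between Hounsfield units and linear attenuation
#'
#' `mu = mu_water * (1 + HU / 1000)`, clipped at 0 (air at -1000 HU maps to
#' zero attenuation; nothing attenuates negatively). `mu_water` defaults to
#' 0.0206 / mm, a typical value around 60-70 keV effective energy.
#'
#' @param image a `ct_image` in the HU (or ATTENUATION) domain.
#' @param mu_water linear attenuation of water in 1/mm.
#' @return a `ct_image` in the complementary domain.
#' @export
hu_to_attenuation <- function(image, mu_water = 0.0206) {
  .assert_domain(image, "HU")
  out <- image
  out$pixels <- pmax(mu_water * (1 + image$pixels / 1000), 0)
  out$domain <- "ATTENUATION"
  out
}

#' @rdname hu_to_attenuation
#' @export
attenuation_to_hu <- function(image, mu_water = 0.0206) {
  .assert_domain(image, "ATTENUATION")
  out <- image
  out$pixels <- 1000 * (image$pixels / mu_water - 1)
  out$domain <- "HU"
  out
}

# bilinear sample of matrix `img` at fractional (row, col); zero outside
.bilinear <- function(img, r, c) {
  m <- nrow(img); n <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- ri >= 1 & ri <= m & ci >= 1 & ci <= n & wgt > 0
    if (any(ok)) val[ok] <- val[ok] + wgt[ok] * img[cbind(ri[ok], ci[ok])]
  }
  val
}

#' Parallel-beam Radon transform
#'
#' Line integrals of an attenuation image over `n_angles` equi-spaced
#' projection angles in `[0, pi)`. Rays are sampled at one-pixel steps with
#' bilinear interpolation (zero outside the image), and integrals are
#' scaled by the pixel spacing so the result is dimensionless optical
#' depth. The operator is linear in the image.
#'
#' @param image a `ct_image` in the ATTENUATION domain.
#' @param n_angles number of projection angles (>= 1).
#' @param n_detectors number of detector bins; defaults to the image
#'   diagonal in pixels (rounded up to odd so a central bin exists).
#' @return a [sinogram()] in the LINE_INTEGRAL domain.
#' @export
radon_transform <- function(image, n_angles = 180L, n_detectors = NULL) {
  .assert_domain(image, "ATTENUATION")
  if (n_angles < 1L) stop("need at least one projection angle")
  img <- image$pixels
  m <- nrow(img); n <- ncol(img)
  if (is.null(n_detectors)) {
    n_detectors <- ceiling(sqrt(m^2 + n^2))
    if (n_detectors %% 2L == 0L) n_detectors <- n_detectors + 1L
  }
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  cy <- (m + 1) / 2; cx <- (n + 1) / 2
  t <- seq_len(n_detectors) - (n_detectors + 1) / 2   # detector coordinate, px
  s <- t                                              # sample coordinate along ray
  vals <- matrix(0, n_angles, n_detectors)
  tg <- rep(t, times = length(s))
  sg <- rep(s, each = length(t))
  for (a in seq_len(n_angles)) {
    th <- angles[a]
    # detector axis (cos, sin), ray direction (-sin, cos) in (x, y)
    x <- tg * cos(th) - sg * sin(th)
    y <- tg * sin(th) + sg * cos(th)
    sm <- .bilinear(img, cy + y, cx + x)
    vals[a, ] <- rowSums(matrix(sm, length(t), length(s)))
  }
  sinogram(pmax(vals * image$pixel_spacing, 0), angles,
           detector_spacing = image$pixel_spacing, domain = "LINE_INTEGRAL")
}

# Poisson draws that stay exact for small rates and switch to the
# (rounded, floored) normal limit for rates beyond integer range
.rpois_large <- function(lambda) {
  out <- numeric(length(lambda))
  small <- lambda <= 1e7
  if (any(small)) out[small] <- rpois(sum(small), lambda[small])
  if (any(!small))
    out[!small] <- pmax(round(lambda[!small] +
                              sqrt(lambda[!small]) * rnorm(sum(!small))), 0)
  out
}

#' Insert projection-domain quantum noise
#'
#' Applies the photon-counting model: for each sinogram bin with line
#' integral `p`, draws `c = K * Poisson(N0 * dose_fraction * exp(-p))`.
#' Reducing `dose_fraction` reduces the incident flux and so raises the
#' relative noise as `1/sqrt(dose_fraction)`. Reproducible: the draw is
#' seeded from `dose$seed`.
#'
#' @param sino a LINE_INTEGRAL [sinogram()].
#' @param dose a [dose_model()].
#' @return a COUNTS sinogram.
#' @export
add_quantum_noise <- function(sino, dose) {
  if (!inherits(sino, "sinogram") || sino$domain != "LINE_INTEGRAL")
    stop("`sino` must be a LINE_INTEGRAL sinogram")
  if (any(sino$values < 0)) stop("negative line integrals")
  n0_eff <- dose$N0 * dose$dose_fraction
  rates <- n0_eff * exp(-sino$values)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(dose$seed)
  counts <- dose$K * .rpois_large(as.vector(rates))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out <- sino
  out$values <- matrix(counts, nrow(sino$values), ncol(sino$values))
  out$domain <- "COUNTS"
  out
}

#' Log-convert photon counts back to line integrals
#'
#' Inverts the exponential attenuation: `p_hat = -log(max(c / K, c_min) /
#' N0_eff)` with a photon-starvation floor of `c_min = 1` count so zero
#' counts stay finite.
#'
#' @inheritParams add_quantum_noise
#' @param c_min count floor (default 1).
#' @return a LINE_INTEGRAL sinogram.
#' @export
counts_to_line_integrals <- function(sino, dose, c_min = 1) {
  if (!inherits(sino, "sinogram") || sino$domain != "COUNTS")
    stop("`sino` must be a COUNTS sinogram")
  n0_eff <- dose$N0 * dose$dose_fraction
  p <- -log(pmax(sino$values / dose$K, c_min) / n0_eff)
  out <- sino
  out$values <- pmax(p, 0)
  out$domain <- "LINE_INTEGRAL"
  out
}

#' Filtered back-projection reconstruction
#'
#' Standard parallel-beam FBP: each projection is ramp-filtered in the
#' frequency domain (optionally Hann-apodized to trade resolution for noise
#' suppression), then back-projected pixel-driven with linear interpolation
#' and scaled by `pi / n_angles`. Linear in the sinogram. Using fewer than
#' 8 angles triggers a degraded-quality warning (not an error).
#'
#' @param sino a LINE_INTEGRAL [sinogram()].
#' @param filter `"ramp"` or `"hann"`.
#' @param output_size reconstructed image side length in pixels; defaults
#'   to the largest square inscribed in the detector extent.
#' @return a `ct_image` in the ATTENUATION domain.
#' @export
fbp <- function(sino, filter = c("ramp", "hann"), output_size = NULL) {
  filter <- match.arg(filter)
  if (!inherits(sino, "sinogram") || sino$domain != "LINE_INTEGRAL")
    stop("`sino` must be a LINE_INTEGRAL sinogram")
  n_angles <- nrow(sino$values)
  if (n_angles < 8L)
    warning("fewer than 8 projection angles: reconstruction quality degraded")
  nd <- ncol(sino$values)
  dt <- sino$detector_spacing
  if (is.null(output_size)) output_size <- floor(nd / sqrt(2))
  # ramp filter on zero-padded projections
  npad <- 2^ceiling(log2(2 * nd))
  freq <- c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * dt)
  H <- abs(freq)
  if (filter == "hann") {
    fn <- max(abs(freq))
    H <- H * 0.5 * (1 + cos(pi * freq / fn))
  }
  P <- rbind(t(sino$values), matrix(0, npad - nd, n_angles))
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / npad
  Q <- Q[seq_len(nd), , drop = FALSE]     # filtered projections, det x angle
  m <- output_size
  cy <- (m + 1) / 2
  xs <- ((seq_len(m)) - cy) * dt
  X <- matrix(rep(xs, each = m), m, m)    # column coords (x)
  Y <- matrix(rep(xs, times = m), m, m)   # row coords (y)
  tc <- (nd + 1) / 2
  img <- matrix(0, m, m)
  for (a in seq_len(n_angles)) {
    th <- sino$angles[a]
    tpos <- (X * cos(th) + Y * sin(th)) / dt + tc
    i0 <- floor(tpos); f <- tpos - i0
    ok0 <- i0 >= 1 & i0 <= nd
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nd
    acc <- matrix(0, m, m)
    q <- Q[, a]
    acc[ok0] <- acc[ok0] + (1 - f[ok0]) * q[i0[ok0]]
    acc[ok1] <- acc[ok1] + f[ok1] * q[i0[ok1] + 1]
    img <- img + acc
  }
  img <- img * pi / n_angles
  ct_image(img, domain = "ATTENUATION", pixel_spacing = dt)
}

#' Simulate a low-dose acquisition from a normal-dose image
#'
#' Full projection-domain pipeline: HU to attenuation, Radon transform,
#' Poisson counting noise at the configured dose, log conversion back to
#' line integrals, FBP reconstruction, and conversion back to HU. The
#' output noise level scales as `1/sqrt(N0 * dose_fraction)`; the result is
#' deterministic given `dose$seed`. Note that even at full dose the output
#' differs slightly from the input because of the discrete Radon/FBP round
#' trip; noiseless references for comparison should be produced with
#' `dose_fraction = 1` and very large `N0`.
#'
#' @param ndct a `ct_image` in the HU domain (normal-dose reference).
#' @param dose a [dose_model()].
#' @param n_angles projection angles (default 180).
#' @param filter FBP filter (default `"ramp"`).
#' @param mu_water attenuation of water, 1/mm.
#' @return a `ct_image` in the HU domain with the same shape as `ndct`.
#' @export
simulate_ldct <- function(ndct, dose, n_angles = 180L, filter = "ramp",
                          mu_water = 0.0206) {
  .assert_domain(ndct, "HU", "ndct")
  att <- hu_to_attenuation(ndct, mu_water)
  sino <- radon_transform(att, n_angles = n_angles)
  noisy <- add_quantum_noise(sino, dose)
  logd <- counts_to_line_integrals(noisy, dose)
  rec <- fbp(logd, filter = filter, output_size = max(dim(ndct$pixels)))
  rec$pixels <- rec$pixels[seq_len(nrow(ndct$pixels)),
                           seq_len(ncol(ndct$pixels)), drop = FALSE]
  attenuation_to_hu(rec, mu_water)
}

#' Fast image-domain Poisson noise insertion
#'
#' Direct noise injection without the projection round trip, in the style
#' used to synthesize reduced-dose series from normal-dose reconstructions:
#' each pixel's HU value is mapped to attenuation, converted to a
#' transmitted-intensity proxy `I = N0_eff * exp(-mu * L_eff)` for an
#' effective path length `L_eff`, Poisson-thinned, and mapped back. This is
#' a documented approximation — noise is made spatially independent rather
#' than reconstruction-correlated — useful when the full simulator is too
#' slow.
#'
#' @inheritParams simulate_ldct
#' @param L_eff effective path length in mm controlling how strongly the
#'   noise grows with attenuation (default 30).
#' @return a `ct_image` in the HU domain.
#' @export
inject_image_noise <- function(ndct, dose, L_eff = 30, mu_water = 0.0206) {
  .assert_domain(ndct, "HU", "ndct")
  mu <- pmax(mu_water * (1 + ndct$pixels / 1000), 0)
  n0_eff <- dose$N0 * dose$dose_fraction
  rates <- n0_eff * exp(-mu * L_eff)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(dose$seed)
  counts <- pmax(.rpois_large(as.vector(rates)), 1)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  mu_hat <- -log(matrix(counts, nrow(mu), ncol(mu)) / n0_eff) / L_eff
  out <- ndct
  out$pixels <- 1000 * (mu_hat / mu_water - 1)
  out
}
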