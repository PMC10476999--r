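# Independent brute-force oracles, deliberately avoiding stats::fft and the
# package's frequency code paths.

# naive double-sum 2-D DFT: F(u,v) = sum_xy f(x,y) exp(-2pi i (ux/m + vy/n))
oracle_dft2 <- function(f) {
  m <- nrow(f); n <- ncol(f)
  out <- matrix(complex(real = 0), m, n)
  for (u in 0:(m - 1)) for (v in 0:(n - 1)) {
    ph <- outer(0:(m - 1) * u / m, 0:(n - 1) * v / n, `+`)
    out[u + 1, v + 1] <- sum(f * exp(-2i * pi * ph))
  }
  out
}

oracle_idft2 <- function(F) {
  m <- nrow(F); n <- ncol(F)
  out <- matrix(complex(real = 0), m, n)
  for (x in 0:(m - 1)) for (y in 0:(n - 1)) {
    ph <- outer(0:(m - 1) * x / m, 0:(n - 1) * y / n, `+`)
    out[x + 1, y + 1] <- sum(F * exp(2i * pi * ph)) / (m * n)
  }
  out
}

# ideal high-pass mask by direct enumeration of centered radii
oracle_ideal_mask <- function(m, n, r0) {
  mask <- matrix(1, m, n)
  for (u in 0:(m - 1)) for (v in 0:(n - 1)) {
    uc <- ((u + m %/% 2) %% m) - m %/% 2
    vc <- ((v + n %/% 2) %% n) - n %/% 2
    if (sqrt((uc / m)^2 + (vc / n)^2) <= r0) mask[u + 1, v + 1] <- 0
  }
  mask[1, 1] <- 0
  mask
}

oracle_hf_loss <- function(g, t, r0) {
  msk <- oracle_ideal_mask(nrow(g), ncol(g), r0)
  hg <- Re(oracle_idft2(msk * oracle_dft2(g)))
  ht <- Re(oracle_idft2(msk * oracle_dft2(t)))
  mean(abs(hg - ht))
}

# builds an image pair whose 2x2-grid patch MAEs are exactly `maes`
patch_mae_fixture <- function(maes, patch = 4L) {
  s <- 2L * patch
  g <- matrix(0, s, s)
  t <- g
  t[1:patch, 1:patch] <- maes[1]
  t[1:patch, (patch + 1):s] <- maes[2]
  t[(patch + 1):s, 1:patch] <- maes[3]
  t[(patch + 1):s, (patch + 1):s] <- maes[4]
  list(generated = g, target = t)
}

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xm <- x
    xp[i, j] <- x[i, j] + h
    xm[i, j] <- x[i, j] - h
    g[i, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
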