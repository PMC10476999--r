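# Shared fixtures built once per test run. The demo dataset (30 phantom
# pairs at quarter dose through the projection-domain simulator) backs both
# the trainer tests and the end-to-end smoke ablation.

.fixture_cache <- new.env(parent = emptyenv())

demo_dataset <- function() {
  if (is.null(.fixture_cache$data)) {
    dir <- file.path(tempdir(), "ldctloss-demo-data")
    if (!file.exists(file.path(dir, "manifest.json")))
      generate_dataset(30, dir, spec = phantom_spec(size = 64),
                       dose = dose_model(N0 = 1e5, dose_fraction = 0.25),
                       master_seed = 7, n_angles = 90)
    .fixture_cache$data <- load_dataset(dir)
  }
  .fixture_cache$data
}

# desk-scale training configuration used by the smoke tests
smoke_config <- function(loss = "hybrid", epochs = 25L, seed = 3L) {
  train_config(loss = loss, epochs = epochs, learning_rate = 1e-3,
               batch_size = 1L, seed = seed)
}

# radially symmetric Gaussian blob, decayed fast enough that the square
# image support carries no appreciable mass near the corners
smooth_attenuation_phantom <- function(s = 128L, mu = 0.02) {
  xs <- (1:s - (s + 1) / 2) / (s / 2)
  r2 <- outer(xs^2, xs^2, `+`)
  ct_image(mu * exp(-6 * r2), domain = "ATTENUATION")
}
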