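# Small in-code fixtures shared across test files.

tiny_spectra <- function(n = 3, p = 5, seed = 42) {
  set.seed(seed)
  spectra_matrix(matrix(round(rnorm(n * p), 6), n, p),
                 wavenumbers = seq(2000, by = -4, length.out = p))
}

# A small single-band world. Default: light corruption; clean = TRUE turns
# every corruption off (truly noise-free Beer-Lambert data).
small_world <- function(n = 40, seed = 3, noise = 0.001, clean = FALSE) {
  cfg <- synthetic_config(
    n_samples = n, seed = seed,
    analyte_bands = list(band_spec(1200, 80, 0.01)),
    interferent_bands = list(),
    interferent_conc_sd = 0,
    baseline_offset_sd = if (clean) 0 else 0.002,
    scatter_sd = if (clean) 0 else 0.02,
    noise_sd = noise,
    wavenumber_grid = c(1600, 800, 8))
  gen <- generate_spectra(cfg)
  y <- gen$truth$concentrations
  list(X = gen$spectra$intensities, y = as.numeric(y), spectra = gen$spectra,
       cfg = cfg)
}

# Deterministic multi-source matrix for model-level tests (no file I/O).
scores_regression_case <- function(n = 30, A = 2, seed = 5) {
  set.seed(seed)
  T <- matrix(rnorm(n * A), n, A)
  y <- drop(sin(T[, 1]) + 0.5 * T %*% rep(1, A)) + rnorm(n, sd = 0.01)
  list(T = T, y = y)
}

write_tmp_jcamp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".jdx",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
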