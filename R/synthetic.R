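#' @keywords internal
#' Derive a reproducible sub-stream seed from a global seed and operation tag.
#' Keeps all derived seeds in [0, 2^31 - 2] so they stay valid R integers.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (31L^(seq_along(utf8ToInt(tag)) %% 7L)))
  as.integer((as.double(seed) * 2654435.0 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe a Gaussian absorption band
#'
#' @param center band centre, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param amplitude peak absorbance; for analyte bands this is absorbance per
#'   mg L^-1 (Beer-Lambert proportionality), for interferent bands an absolute
#'   absorbance.
#' @return a `band_spec` list.
#' @export
band_spec <- function(center, width, amplitude) {
  if (width <= 0) stop("band_spec: width must be > 0")
  if (amplitude < 0) stop("band_spec: amplitude must be >= 0")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

band_profile <- function(band, wavenumbers) {
  band$amplitude * exp(-(wavenumbers - band$center)^2 / (2 * band$width^2))
}

#' Default configuration for the synthetic ATR-IR experiment
#'
#' The defaults state the world the pipeline is verified against: 198 aqueous
#' samples with iron concentrations spanning 0.5-25 mg L^-1, spectra on the
#' instrument grid 4000 -> 400 cm^-1 at 4 cm^-1 steps, three overlapping
#' analyte bands in the 1500-900 cm^-1 fingerprint region, and three dominant
#' matrix/excipient ("interferent") bands overlapping them whose levels vary
#' about 12% from sample to sample. The matrix bands dwarf the analyte
#' signal, as the water/excipient background does in ATR-IR of aqueous
#' formulations; because SNV discards the absolute intensity scale, they
#' also act as the internal reference the calibration implicitly ratios
#' against, so their level variability bounds the attainable accuracy.
#' SNV collapses one degree of freedom (the overall scale), leaving a
#' three-dimensional information manifold — exactly the three informative
#' latent directions that make one latent variable underfit badly and three
#' suffice. Per-sample additive
#' baseline offsets and multiplicative scatter (the corruption SNV removes
#' exactly) and additive instrument noise complete the picture.
#'
#' @param n_samples number of samples.
#' @param conc_range concentration range `c(low, high)` in mg L^-1.
#' @param analyte_bands list of [band_spec()]s scaling with concentration.
#' @param interferent_bands list of [band_spec()]s with per-sample random
#'   levels `z ~ N(1, interferent_conc_sd)`.
#' @param interferent_conc_sd sd of interferent levels (dimensionless).
#' @param baseline_offset_sd sd of the per-sample additive baseline
#'   (absorbance units).
#' @param scatter_sd sd of the per-sample multiplicative scatter factor
#'   (mean 1, truncated below at 0.1).
#' @param noise_sd sd of iid additive noise per channel (absorbance units).
#' @param wavenumber_grid `c(start, stop, step)` in cm^-1; step must divide
#'   `start - stop`.
#' @param seed global integer seed; every stochastic draw flows from a
#'   sub-stream derived from it and an operation tag.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_samples = 198L,
    conc_range = c(0.5, 25),
    analyte_bands = list(
      band_spec(1430, 60, 0.012),
      band_spec(1240, 45, 0.018),
      band_spec(1060, 50, 0.015)
    ),
    interferent_bands = list(
      band_spec(1425, 75, 1.00),
      band_spec(1235, 60, 0.70),
      band_spec(1065, 70, 0.80)
    ),
    interferent_conc_sd = 0.12,
    baseline_offset_sd = 0.005,
    scatter_sd = 0.10,
    noise_sd = 0.001,
    wavenumber_grid = c(4000, 400, 4),
    seed = 1L) {
  if (n_samples < 1L) stop("synthetic_config: n_samples must be >= 1")
  if (length(conc_range) != 2L || conc_range[1] >= conc_range[2])
    stop("synthetic_config: conc_range must satisfy low < high")
  sds <- c(interferent_conc_sd, baseline_offset_sd, scatter_sd, noise_sd)
  if (any(sds < 0)) stop("synthetic_config: standard deviations must be >= 0")
  g <- wavenumber_grid
  if (length(g) != 3L || g[3] <= 0)
    stop("synthetic_config: wavenumber_grid must be c(start, stop, step), step > 0")
  span <- abs(g[1] - g[2])
  if (abs(span / g[3] - round(span / g[3])) > 1e-9)
    stop("synthetic_config: step must divide start - stop")
  structure(list(
    n_samples = as.integer(n_samples), conc_range = as.numeric(conc_range),
    analyte_bands = analyte_bands, interferent_bands = interferent_bands,
    interferent_conc_sd = interferent_conc_sd,
    baseline_offset_sd = baseline_offset_sd, scatter_sd = scatter_sd,
    noise_sd = noise_sd, wavenumber_grid = as.numeric(g),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

grid_wavenumbers <- function(g) {
  if (g[1] >= g[2]) seq(g[1], g[2], by = -g[3]) else seq(g[1], g[2], by = g[3])
}

#' Draw calibration concentrations spanning a range
#'
#' Stratified-uniform: the range is cut into `n` equal-width bins, one uniform
#' draw is taken per bin, and the result is shuffled. This guarantees coverage
#' of the full calibration range, the way a bench scientist would lay out
#' standards, rather than leaving chance gaps as plain uniform sampling can.
#'
#' @param n number of samples.
#' @param range `c(low, high)` mg L^-1, `low < high`.
#' @param seed integer seed.
#' @return a [response_vector()].
#' @export
sample_concentrations <- function(n, range = c(0.5, 25), seed = 1L) {
  if (n < 1L) stop("sample_concentrations: n must be >= 1")
  if (range[1] >= range[2])
    stop("sample_concentrations: range must satisfy low < high")
  with_seed(derive_seed(seed, "sample_concentrations"), {
    edges <- seq(range[1], range[2], length.out = n + 1L)
    vals <- stats::runif(n, edges[-(n + 1L)], edges[-1L])
    vals <- vals[sample.int(n)]
  })
  response_vector(vals)
}

#' Generate synthetic ATR-IR spectra with recorded ground truth
#'
#' Each spectrum is built as
#' `scatter_i * (c_i * analyte(v) + sum_k z_ik * interferent_k(v)) +
#'  baseline_i + noise`, where the analyte term follows Beer-Lambert
#' linearity in the concentration `c_i`, `z_ik ~ N(1, interferent_conc_sd)`,
#' `scatter_i ~ N(1, scatter_sd)` truncated below at 0.1,
#' `baseline_i ~ N(0, baseline_offset_sd)` and the noise is iid
#' `N(0, noise_sd)` per channel. All latent draws are returned so a run can be
#' reconstructed exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `spectra` (a [spectra_matrix()]), and `truth` (list:
#'   `concentrations`, `baselines`, `scatters`, `interferent_levels`,
#'   `noise`).
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  w <- grid_wavenumbers(cfg$wavenumber_grid)
  wr <- range(w)
  for (b in c(cfg$analyte_bands, cfg$interferent_bands)) {
    if (b$center < wr[1] || b$center > wr[2])
      stop("generate_spectra: band center ", b$center,
           " cm^-1 lies outside the wavenumber grid")
  }
  n <- cfg$n_samples
  p <- length(w)
  conc <- sample_concentrations(n, cfg$conc_range, cfg$seed)

  analyte_shape <- rep(0, p)
  for (b in cfg$analyte_bands) analyte_shape <- analyte_shape + band_profile(b, w)
  k <- length(cfg$interferent_bands)
  interf_shapes <- if (k)
    vapply(cfg$interferent_bands, band_profile, numeric(p), wavenumbers = w)
  else matrix(0, p, 0L)

  z <- with_seed(derive_seed(cfg$seed, "interferent_levels"), {
    matrix(stats::rnorm(n * k, mean = 1, sd = cfg$interferent_conc_sd), n, k)
  })
  scatters <- with_seed(derive_seed(cfg$seed, "scatter"), {
    pmax(stats::rnorm(n, mean = 1, sd = cfg$scatter_sd), 0.1)
  })
  baselines <- with_seed(derive_seed(cfg$seed, "baseline"), {
    stats::rnorm(n, mean = 0, sd = cfg$baseline_offset_sd)
  })
  noise <- with_seed(derive_seed(cfg$seed, "noise"), {
    matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
  })

  clean <- outer(as.numeric(conc), analyte_shape)
  if (k) clean <- clean + z %*% t(interf_shapes)
  intens <- clean * scatters + baselines + noise

  spectra <- spectra_matrix(intens, w, names(conc))
  list(spectra = spectra,
       truth = list(concentrations = conc, baselines = baselines,
                    scatters = scatters, interferent_levels = z,
                    noise = noise))
}

#' Rebuild the spectra matrix from recorded ground-truth latents
#'
#' Useful for verifying that the latents fully determine the generated data.
#'
#' @param cfg the [synthetic_config()] used for generation.
#' @param truth the `truth` component returned by [generate_spectra()].
#' @return a [spectra_matrix()] identical to the generated one.
#' @export
rebuild_from_truth <- function(cfg, truth) {
  w <- grid_wavenumbers(cfg$wavenumber_grid)
  p <- length(w)
  analyte_shape <- rep(0, p)
  for (b in cfg$analyte_bands) analyte_shape <- analyte_shape + band_profile(b, w)
  k <- length(cfg$interferent_bands)
  clean <- outer(as.numeric(truth$concentrations), analyte_shape)
  if (k) {
    interf_shapes <- vapply(cfg$interferent_bands, band_profile, numeric(p),
                            wavenumbers = w)
    clean <- clean + truth$interferent_levels %*% t(interf_shapes)
  }
  intens <- clean * truth$scatters + truth$baselines + truth$noise
  spectra_matrix(intens, w, names(truth$concentrations))
}

#' Simulate AAS absorbance readings for known concentrations
#'
#' A linear instrument response `a = slope * c + intercept + N(0, noise_sd)`,
#' the Beer-Lambert regime the reference method is operated in.
#'
#' @param conc a [response_vector()] or numeric vector of concentrations.
#' @param slope absorbance per mg L^-1, must be > 0.
#' @param intercept blank absorbance.
#' @param noise_sd sd of the reading noise (absorbance units).
#' @param seed integer seed.
#' @return numeric vector of absorbances, named by sample ID when available.
#' @export
generate_aas_absorbance <- function(conc, slope = 0.032, intercept = 0.001,
                                    noise_sd = 0.002, seed = 1L) {
  if (slope <= 0) stop("generate_aas_absorbance: slope must be > 0")
  c_num <- as.numeric(conc)
  a <- with_seed(derive_seed(seed, "aas"), {
    slope * c_num + intercept + stats::rnorm(length(c_num), sd = noise_sd)
  })
  names(a) <- names(conc)
  a
}

#' Back-calculate concentrations from AAS absorbances
#'
#' The modelling response is the AAS-derived concentration
#' `c_ref = (a - intercept) / slope`, i.e. the true concentration plus
#' reference-method noise — this is the `y` the calibration model actually
#' sees in practice. Negative back-calculations (possible at the blank end)
#' are clipped at zero.
#'
#' @param absorbance numeric AAS readings.
#' @param slope,intercept the instrument line used to invert.
#' @return a [response_vector()].
#' @export
aas_to_concentration <- function(absorbance, slope = 0.032,
                                 intercept = 0.001) {
  if (slope <= 0) stop("aas_to_concentration: slope must be > 0")
  vals <- pmax((as.numeric(absorbance) - intercept) / slope, 0)
  response_vector(vals, names(absorbance))
}
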