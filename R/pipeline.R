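#' Configuration for a full pipeline run
#'
#' Aggregates every stage setting: the synthetic-data world (or file inputs),
#' the calibration-set size, the LV scan range, hyperparameter grids, the
#' cross-validation and permutation settings and the global seed. Defaults
#' follow the reference workflow: 198 samples split 158/40 by Kennard-Stone,
#' LVs scanned over 1-10, 20% leave-many-out, 100 permutations.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when `spectra_file` and
#'   `response_file` are given.
#' @param spectra_file,response_file optional CSV inputs used instead of
#'   generation.
#' @param n_cal calibration-set size (default 158).
#' @param lv_range LV counts to scan (default 1:10).
#' @param gamma_grid,sigma2_grid optional hyperparameter grids; `NULL` means
#'   [default_grids()].
#' @param lmo_fraction leave-many-out fraction (default 0.2).
#' @param lmo_repeats LMO rounds (default 25).
#' @param n_permutations permutation count (default 100).
#' @param permutation_cv whether permutations also run LOO/LMO (default
#'   `TRUE`; the expensive part of the report).
#' @param aas_slope,aas_intercept,aas_noise_sd synthetic AAS reference-channel
#'   line and noise.
#' @param seed global seed.
#' @param output_dir where artifacts are written (`NULL` = nowhere).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            spectra_file = NULL, response_file = NULL,
                            n_cal = 158L, lv_range = 1:10,
                            gamma_grid = NULL, sigma2_grid = NULL,
                            lmo_fraction = 0.2, lmo_repeats = 25L,
                            n_permutations = 100L, permutation_cv = TRUE,
                            aas_slope = 0.032, aas_intercept = 0.001,
                            aas_noise_sd = 0.002,
                            seed = 1L, output_dir = NULL) {
  use_files <- !is.null(spectra_file) || !is.null(response_file)
  if (use_files) {
    if (is.null(spectra_file) || is.null(response_file))
      stop("pipeline_config: need both spectra_file and response_file")
    if (!file.exists(spectra_file))
      stop("pipeline_config: spectra_file not found: ", spectra_file)
    if (!file.exists(response_file))
      stop("pipeline_config: response_file not found: ", response_file)
    synthetic <- NULL
  } else if (is.null(synthetic)) {
    stop("pipeline_config: provide a synthetic config or input files")
  }
  structure(list(
    synthetic = synthetic, spectra_file = spectra_file,
    response_file = response_file, n_cal = as.integer(n_cal),
    lv_range = as.integer(lv_range), gamma_grid = gamma_grid,
    sigma2_grid = sigma2_grid, lmo_fraction = lmo_fraction,
    lmo_repeats = as.integer(lmo_repeats),
    n_permutations = as.integer(n_permutations),
    permutation_cv = isTRUE(permutation_cv),
    aas_slope = aas_slope, aas_intercept = aas_intercept,
    aas_noise_sd = aas_noise_sd,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Flat key-value file mirroring the [pipeline_config()] arguments; nested
#' `synthetic:` keys mirror [synthetic_config()] (band lists as arrays of
#' `[center, width, amplitude]` triplets).
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_pipeline_config: the 'yaml' package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    to_bands <- function(b) lapply(seq_len(nrow(b)), function(i)
      band_spec(b[i, 1], b[i, 2], b[i, 3]))
    for (f in c("analyte_bands", "interferent_bands"))
      if (!is.null(syn[[f]])) syn[[f]] <- to_bands(as.matrix(syn[[f]]))
    args$synthetic <- do.call(synthetic_config, syn)
  }
  do.call(pipeline_config, args)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

#' Run the full calibration pipeline
#'
#' Stages, in order: generate (or load) spectra and reference responses; SNV
#' preprocess; Kennard-Stone split; hyperparameter tuning by LOO PRESS on the
#' calibration set; LV-count selection; per-LV validation report with LOO and
#' LMO cross-validation; external validation on the untouched test set;
#' Y-permutation test. Every stochastic stage draws from a sub-stream of the
#' global seed, so re-running the same config reproduces every artifact
#' byte-for-byte.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log one line per stage (default `TRUE`).
#' @return a `pipeline_result` list: `report` (a `validation_report`),
#'   `model` (the final `hybrid_model`), `split`, `tuning`, `lv_selection`,
#'   `spectra`, `response`, `config`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()

  if (!is.null(cfg$spectra_file)) {
    spectra <- read_spectra_csv(cfg$spectra_file)
    y <- read_response_csv(cfg$response_file)
    truth <- NULL
    log_stage(verbose, "load", "read ", nrow(spectra$intensities),
              " spectra from ", cfg$spectra_file)
  } else {
    gen <- generate_spectra(cfg$synthetic)
    spectra <- gen$spectra
    truth <- gen$truth
    aas <- generate_aas_absorbance(truth$concentrations, cfg$aas_slope,
                                   cfg$aas_intercept, cfg$aas_noise_sd,
                                   seed = cfg$synthetic$seed)
    y <- aas_to_concentration(aas, cfg$aas_slope, cfg$aas_intercept)
    log_stage(verbose, "generate", cfg$synthetic$n_samples, " samples x ",
              ncol(spectra$intensities), " wavenumbers, seed ",
              cfg$synthetic$seed)
  }
  check_paired(spectra, y)

  snv <- snv_matrix(spectra)
  log_stage(verbose, "preprocess", "SNV applied to ",
            nrow(snv$intensities), " spectra")

  split <- kennard_stone(snv, cfg$n_cal)
  parts <- apply_split(snv, y, split)
  log_stage(verbose, "split", "Kennard-Stone: ", length(split$calibration),
            " calibration / ", length(split$test), " test")

  # LV used during gamma/sigma2 tuning: middle of the scanned range
  a_tune <- cfg$lv_range[ceiling(length(cfg$lv_range) / 2)]
  tuning <- tune_hyperparameters(parts$cal_x, parts$cal_y, a_tune,
                                 cfg$gamma_grid, cfg$sigma2_grid)
  log_stage(verbose, "tune", "gamma = ", tuning$gamma, ", sigma2 = ",
            format(tuning$sigma2, digits = 4), " (LOO PRESS = ",
            format(tuning$press, digits = 4), ", tuned at A = ", a_tune, ")")

  sel <- select_n_lv(parts$cal_x, parts$cal_y, cfg$lv_range,
                     tuning$gamma, tuning$sigma2)
  log_stage(verbose, "select_lv", "chosen A = ", sel$chosen_lv)

  perm <- NULL
  if (cfg$n_permutations >= 1L) {
    perm <- y_permutation_test(parts$cal_x, parts$cal_y, sel$chosen_lv,
                               tuning$gamma, tuning$sigma2,
                               B = cfg$n_permutations, seed = cfg$seed,
                               include_cv = cfg$permutation_cv)
    log_stage(verbose, "permutation", cfg$n_permutations,
              " scrambles, max permuted r^2 = ",
              format(max(perm$permuted_r2), digits = 4))
  }

  report_lvs <- sort(unique(c(
    cfg$lv_range[cfg$lv_range <= 3L], sel$chosen_lv)))
  report <- build_report(parts$cal_x, parts$cal_y, report_lvs, sel$chosen_lv,
                         tuning$gamma, tuning$sigma2,
                         X_test = parts$test_x, y_test = parts$test_y,
                         permutation = perm,
                         lmo_repeats = cfg$lmo_repeats,
                         lmo_fraction = cfg$lmo_fraction, seed = cfg$seed)
  model <- hybrid_fit(parts$cal_x, parts$cal_y, sel$chosen_lv,
                      tuning$gamma, tuning$sigma2)
  log_stage(verbose, "report", "external r^2 = ",
            if (is.null(report$external)) "NA"
            else format(report$external$r_squared, digits = 4))

  result <- structure(list(
    report = report, model = model, split = split, tuning = tuning,
    lv_selection = sel, spectra = spectra, snv = snv, response = y,
    truth = truth, config = cfg,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "pipeline_result")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$output_dir, f)
    if (is.null(cfg$spectra_file)) {
      write_spectra_csv(spectra, out("spectra.csv"))
      write_response_csv(y, out("response.csv"))
    }
    write_spectra_csv(snv, out("spectra_snv.csv"))
    jsonlite::write_json(list(calibration = split$calibration,
                              test = split$test),
                         out("split.json"), pretty = TRUE)
    write_report_json(report, out("report.json"))
    writeLines(run_log_lines(result), out("run_log.txt"))
    log_stage(verbose, "write", "artifacts in ", cfg$output_dir)
  }
  result
}

run_log_lines <- function(res) {
  cfg <- res$config
  c(sprintf("seed: %d", cfg$seed),
    sprintf("R version: %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("n_cal: %d", cfg$n_cal),
    sprintf("lv_range: %s", paste(cfg$lv_range, collapse = ",")),
    sprintf("chosen_lv: %d", res$report$chosen_lv),
    sprintf("gamma: %.17g", res$tuning$gamma),
    sprintf("sigma2: %.17g", res$tuning$sigma2),
    sprintf("lmo_fraction: %g  lmo_repeats: %d", cfg$lmo_fraction,
            cfg$lmo_repeats),
    sprintf("n_permutations: %d", cfg$n_permutations),
    sprintf("elapsed_s: %.1f", res$elapsed_s))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (%.1f s)\n", x$elapsed_s))
  print(x$report)
  invisible(x)
}
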