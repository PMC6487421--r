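#' Fit the hybrid PLS-LS-SVM calibration model
#'
#' NIPALS PLS first compresses the (SNV-processed) spectra into `A` latent
#' variables, denoising the input; the Gaussian-RBF LS-SVM is then trained on
#' those scores against the uncentred response, with the bias term absorbing
#' the offset. New spectra are predicted by projecting onto the latent
#' variables and evaluating the kernel expansion.
#'
#' @param X_cal n x p calibration spectra (matrix or [spectra_matrix()]).
#' @param y_cal calibration responses (mg L^-1).
#' @param A number of latent variables.
#' @param gamma LS-SVM regularisation, > 0.
#' @param sigma2 squared RBF bandwidth, > 0.
#' @return an object of class `hybrid_model`: `pls` (a `pls_model`), `lssvm`
#'   (an `lssvm_model`), `preprocessing_tag`.
#' @export
hybrid_fit <- function(X_cal, y_cal, A, gamma, sigma2) {
  X <- if (inherits(X_cal, "spectra_matrix")) X_cal$intensities
       else as.matrix(X_cal)
  y <- as.numeric(y_cal)
  pls <- nipals_pls_fit(X, y, A)
  lssvm <- lssvm_fit(pls$scores, y, gamma, sigma2)
  structure(list(pls = pls, lssvm = lssvm, preprocessing_tag = "snv"),
            class = "hybrid_model")
}

#' Predict concentrations from spectra with a hybrid model
#'
#' @param object a `hybrid_model`.
#' @param X new spectra rows (same wavenumber grid and preprocessing as the
#'   calibration data; the pipeline applies SNV upstream).
#' @param ... unused.
#' @return numeric predicted concentrations.
#' @export
predict.hybrid_model <- function(object, X, ...) {
  X <- if (inherits(X, "spectra_matrix")) X$intensities else X
  scores <- pls_transform(object$pls, X)
  predict(object$lssvm, scores)
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf(
    "hybrid_model: %d LVs -> RBF LS-SVM (gamma = %.4g, sigma2 = %.4g)\n",
    x$pls$n_lv, x$lssvm$gamma, x$lssvm$sigma2))
  invisible(x)
}

#' Default hyperparameter grids for tuning
#'
#' `gamma` spans 1e0..1e6 in decade steps; `sigma2` is
#' `{0.1, 1, 10, 100}` times the median pairwise squared score distance
#' (the usual median heuristic for RBF bandwidths).
#'
#' @param scores training score matrix used to anchor the sigma2 grid.
#' @return list with `gamma_grid`, `sigma2_grid`.
#' @export
default_grids <- function(scores) {
  scores <- as.matrix(scores)
  d2 <- as.numeric(stats::dist(scores))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  list(gamma_grid = 10^(0:6), sigma2_grid = c(0.1, 1, 10, 100) * med)
}

#' Select LS-SVM hyperparameters by leave-one-out PRESS on the calibration set
#'
#' Every (gamma, sigma2) grid pair is scored by the leave-one-out PRESS of the
#' full hybrid model (PLS refit per fold at fixed `A`); the argmin wins. Ties
#' go to the smallest gamma, then the largest sigma2 — the most strongly
#' regularised candidate. The test set is never touched.
#'
#' @param X_cal,y_cal calibration data.
#' @param A number of latent variables (fixed during tuning).
#' @param gamma_grid,sigma2_grid positive candidate values; defaults from
#'   [default_grids()] on the `A`-component PLS scores.
#' @return list with `gamma`, `sigma2`, `press` (the winning LOO PRESS), and
#'   `table` (a data.frame of all evaluated pairs).
#' @export
tune_hyperparameters <- function(X_cal, y_cal, A, gamma_grid = NULL,
                                 sigma2_grid = NULL) {
  X <- if (inherits(X_cal, "spectra_matrix")) X_cal$intensities
       else as.matrix(X_cal)
  y <- as.numeric(y_cal)
  if (is.null(gamma_grid) || is.null(sigma2_grid)) {
    g <- default_grids(nipals_pls_fit(X, y, A)$scores)
    if (is.null(gamma_grid)) gamma_grid <- g$gamma_grid
    if (is.null(sigma2_grid)) sigma2_grid <- g$sigma2_grid
  }
  if (!length(gamma_grid) || !length(sigma2_grid))
    stop("tune_hyperparameters: empty grid")
  grid <- expand.grid(gamma = gamma_grid, sigma2 = sigma2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  press_vals <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    res <- tryCatch(
      loo_cv(X, y, A, grid$gamma[k], grid$sigma2[k]),
      error = function(e) NULL)
    if (!is.null(res)) press_vals[k] <- res$press
  }
  if (all(is.na(press_vals)))
    stop("tune_hyperparameters: every grid point failed (ill-conditioned); ",
         "tuning failure")
  grid$press <- press_vals
  ok <- which(is.finite(press_vals))
  best_press <- min(press_vals[ok])
  cand <- grid[ok, ][press_vals[ok] == best_press, , drop = FALSE]
  cand <- cand[order(cand$gamma, -cand$sigma2), , drop = FALSE]
  list(gamma = cand$gamma[1L], sigma2 = cand$sigma2[1L],
       press = best_press, table = grid)
}
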