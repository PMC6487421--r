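#' Predicted residual error sum of squares
#'
#' `PRESS = sum((y - yhat)^2)`.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return scalar, squared concentration units (mg^2 L^-2).
#' @export
press <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred))
    stop("press: length mismatch (", length(y_true), " vs ",
         length(y_pred), ")")
  if (!length(y_true)) stop("press: empty vectors")
  sum((y_true - y_pred)^2)
}

#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot`; can be negative for predictions worse than the
#' mean. When held-out predictions are scored this is the Q^2 statistic.
#'
#' @param y_true observed values (non-constant).
#' @param y_pred predictions.
#' @param y_center optional reference mean for SS_tot; defaults to
#'   `mean(y_true)`. Cross-validation metrics in this package use the mean of
#'   the full calibration response.
#' @return scalar <= 1.
#' @export
r2_score <- function(y_true, y_pred, y_center = NULL) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("r2_score: length mismatch")
  if (is.null(y_center)) y_center <- mean(y_true)
  ss_tot <- sum((y_true - y_center)^2)
  if (ss_tot == 0) stop("r2_score: degenerate (constant) y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

metric_set <- function(y_true, y_pred, y_center = NULL) {
  n <- length(y_true)
  p <- press(y_true, y_pred)
  list(r_squared = r2_score(y_true, y_pred, y_center),
       press = p, rmse = sqrt(p / n), n = n)
}

as_matrix_x <- function(X) {
  if (inherits(X, "spectra_matrix")) X$intensities else as.matrix(X)
}

#' Leave-one-out cross-validation of the hybrid model
#'
#' For each calibration sample the full hybrid (PLS at fixed `A`, then LS-SVM
#' at fixed `gamma`, `sigma2`) is refit without it and the held-out sample is
#' predicted. Q^2 is the r^2 of the pooled held-out predictions against the
#' mean of the full calibration response.
#'
#' @param X_cal,y_cal calibration data (n >= 3).
#' @param A,gamma,sigma2 fixed model settings.
#' @return a metric set: `r_squared` (Q^2), `press`, `rmse`, `n`.
#' @export
loo_cv <- function(X_cal, y_cal, A, gamma, sigma2) {
  X <- as_matrix_x(X_cal)
  y <- as.numeric(y_cal)
  n <- nrow(X)
  if (n < 3L) stop("loo_cv: need n >= 3")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      hybrid_fit(X[-i, , drop = FALSE], y[-i], A, gamma, sigma2),
      error = function(e)
        stop("loo_cv: refit failed on fold ", i, ": ", conditionMessage(e)))
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  metric_set(y, preds, y_center = mean(y))
}

#' Leave-many-out (Monte-Carlo) cross-validation
#'
#' `n_repeats` random rounds; each holds out `ceiling(fraction * n)` samples,
#' refits the hybrid on the rest and predicts the held-out block. Metrics are
#' pooled over every held-out prediction across rounds, scored against the
#' full-calibration mean.
#'
#' @param X_cal,y_cal calibration data.
#' @param A,gamma,sigma2 fixed model settings.
#' @param fraction held-out fraction per round, in (0, 1); default 0.2.
#' @param n_repeats number of random rounds (default 25).
#' @param seed integer seed; rounds are reproducible.
#' @return a metric set over the pooled held-out predictions.
#' @export
lmo_cv <- function(X_cal, y_cal, A, gamma, sigma2, fraction = 0.2,
                   n_repeats = 25L, seed = 1L) {
  X <- as_matrix_x(X_cal)
  y <- as.numeric(y_cal)
  n <- nrow(X)
  if (fraction <= 0 || fraction >= 1) stop("lmo_cv: fraction must be in (0,1)")
  if (n_repeats < 1L) stop("lmo_cv: n_repeats must be >= 1")
  m_out <- as.integer(ceiling(fraction * n))
  if (n - m_out < 3L) stop("lmo_cv: too few samples left after holdout")
  holdouts <- with_seed(derive_seed(seed, "lmo_cv"), {
    lapply(seq_len(n_repeats), function(r) sort(sample(n, m_out)))
  })
  y_all <- list(); p_all <- list()
  for (r in seq_len(n_repeats)) {
    out <- holdouts[[r]]
    fit <- tryCatch(
      hybrid_fit(X[-out, , drop = FALSE], y[-out], A, gamma, sigma2),
      error = function(e)
        stop("lmo_cv: refit failed on round ", r, ": ", conditionMessage(e)))
    y_all[[r]] <- y[out]
    p_all[[r]] <- predict(fit, X[out, , drop = FALSE])
  }
  metric_set(unlist(y_all), unlist(p_all), y_center = mean(y))
}

#' Choose the number of latent variables by LOO PRESS
#'
#' Computes the leave-one-out PRESS of the hybrid model for each candidate
#' LV count and picks the smallest `A` whose PRESS lies within 5% of the
#' global minimum — a parsimony rule that avoids buying complexity for
#' negligible gain.
#'
#' @param X_cal,y_cal calibration data.
#' @param lv_range candidate LV counts (default 1:10, capped at the data's
#'   rank limit).
#' @param gamma,sigma2 fixed LS-SVM settings during the scan.
#' @return list with `chosen_lv` and `table` (data.frame: `n_lv`, `q2_loo`,
#'   `press_loo`).
#' @export
select_n_lv <- function(X_cal, y_cal, lv_range = 1:10, gamma, sigma2) {
  X <- as_matrix_x(X_cal)
  y <- as.numeric(y_cal)
  lv_range <- sort(unique(as.integer(lv_range)))
  lv_range <- lv_range[lv_range >= 1 & lv_range <= min(nrow(X) - 2L, ncol(X))]
  if (!length(lv_range)) stop("select_n_lv: empty lv_range")
  tab <- data.frame(n_lv = lv_range, q2_loo = NA_real_, press_loo = NA_real_)
  for (k in seq_along(lv_range)) {
    res <- loo_cv(X, y, lv_range[k], gamma, sigma2)
    tab$q2_loo[k] <- res$r_squared
    tab$press_loo[k] <- res$press
  }
  best <- min(tab$press_loo)
  chosen <- tab$n_lv[which(tab$press_loo <= 1.05 * best)[1L]]
  list(chosen_lv = chosen, table = tab)
}

#' External validation on an untouched test set
#'
#' The fitted model predicts the test spectra; it is never refit. Reported
#' r^2 uses the test responses' own mean as reference, the convention for an
#' external R^2.
#'
#' @param model a fitted `hybrid_model`.
#' @param X_test,y_test test data (non-empty).
#' @return a metric set.
#' @export
external_validation <- function(model, X_test, y_test) {
  stopifnot(inherits(model, "hybrid_model"))
  X <- as_matrix_x(X_test)
  if (is.null(X) || nrow(X) == 0L)
    stop("external_validation: empty test set")
  preds <- predict(model, X)
  metric_set(as.numeric(y_test), preds)
}

#' Y-permutation (y-randomisation) test
#'
#' Refits the hybrid model `B` times with the calibration responses randomly
#' scrambled, recording the training r^2 and (optionally) the LOO and LMO Q^2
#' of each chance model. If the real model's quality could arise by chance,
#' the permuted distributions will reach it; a wide gap certifies the model
#' was not obtained accidentally.
#'
#' @param X_cal,y_cal calibration data.
#' @param A,gamma,sigma2 fixed model settings.
#' @param B number of permutations (>= 1; default 100).
#' @param seed integer seed.
#' @param include_cv also compute per-permutation LOO/LMO Q^2 (costly but
#'   part of the full report); default `TRUE`.
#' @param lmo_repeats LMO rounds per permutation when `include_cv`.
#' @return an object of class `permutation_result`: `observed_r2`,
#'   `permuted_r2`, `permuted_q2_loo`, `permuted_q2_lmo`, `n_permutations`,
#'   `seed`, `exceedance` (share of permuted training r^2 >= observed).
#' @export
y_permutation_test <- function(X_cal, y_cal, A, gamma, sigma2, B = 100L,
                               seed = 1L, include_cv = TRUE,
                               lmo_repeats = 10L) {
  X <- as_matrix_x(X_cal)
  y <- as.numeric(y_cal)
  if (B < 1L) stop("y_permutation_test: B must be >= 1")
  obs_fit <- hybrid_fit(X, y, A, gamma, sigma2)
  observed_r2 <- r2_score(y, predict(obs_fit, X))
  perms <- with_seed(derive_seed(seed, "y_permutation"), {
    lapply(seq_len(B), function(b) sample(length(y)))
  })
  r2s <- q2l <- q2m <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    yp <- y[perms[[b]]]
    fit <- hybrid_fit(X, yp, A, gamma, sigma2)
    r2s[b] <- r2_score(yp, predict(fit, X))
    if (include_cv) {
      q2l[b] <- loo_cv(X, yp, A, gamma, sigma2)$r_squared
      q2m[b] <- lmo_cv(X, yp, A, gamma, sigma2, n_repeats = lmo_repeats,
                       seed = derive_seed(seed, paste0("perm_lmo", b))
                       )$r_squared
    }
  }
  structure(list(
    observed_r2 = observed_r2, permuted_r2 = r2s,
    permuted_q2_loo = q2l, permuted_q2_lmo = q2m,
    n_permutations = as.integer(B), seed = as.integer(seed),
    exceedance = mean(r2s >= observed_r2)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed r^2 = %.4f; %d permutations, max permuted r^2 = %.4f, exceedance = %.3f\n",
    x$observed_r2, x$n_permutations, max(x$permuted_r2), x$exceedance))
  invisible(x)
}

#' Assemble the per-LV validation report
#'
#' Collects, for each candidate LV count, the training (prediction) metrics
#' and the LOO and LMO cross-validation metrics; records the chosen LV count,
#' the external-validation metrics and an optional permutation summary. The
#' text rendering mirrors the conventional calibration-report layout:
#' rows {r^2, PRESS} x {Prediction, LOO, LMO}, one column per LV count.
#'
#' @param X_cal,y_cal calibration data.
#' @param lv_range LV counts to tabulate.
#' @param chosen_lv the selected LV count (must be in `lv_range`).
#' @param gamma,sigma2 fixed LS-SVM settings.
#' @param X_test,y_test optional test data for external validation.
#' @param permutation optional `permutation_result`.
#' @param lmo_repeats,lmo_fraction,seed LMO settings.
#' @return an object of class `validation_report`: `per_lv` (named list by LV
#'   count, each with `prediction`, `loo`, `lmo` metric sets), `chosen_lv`,
#'   `external`, `permutation`.
#' @export
build_report <- function(X_cal, y_cal, lv_range, chosen_lv, gamma, sigma2,
                         X_test = NULL, y_test = NULL, permutation = NULL,
                         lmo_repeats = 25L, lmo_fraction = 0.2, seed = 1L) {
  X <- as_matrix_x(X_cal)
  y <- as.numeric(y_cal)
  if (!(chosen_lv %in% lv_range))
    stop("build_report: chosen_lv must be one of lv_range")
  per_lv <- list()
  for (A in lv_range) {
    fit <- hybrid_fit(X, y, A, gamma, sigma2)
    pred <- metric_set(y, predict(fit, X))
    loo <- loo_cv(X, y, A, gamma, sigma2)
    lmo <- lmo_cv(X, y, A, gamma, sigma2, fraction = lmo_fraction,
                  n_repeats = lmo_repeats, seed = seed)
    per_lv[[as.character(A)]] <- list(prediction = pred, loo = loo, lmo = lmo)
  }
  external <- NULL
  if (!is.null(X_test) && !is.null(y_test)) {
    final <- hybrid_fit(X, y, chosen_lv, gamma, sigma2)
    external <- external_validation(final, X_test, y_test)
  }
  structure(list(per_lv = per_lv, chosen_lv = as.integer(chosen_lv),
                 external = external, permutation = permutation,
                 gamma = gamma, sigma2 = sigma2),
            class = "validation_report")
}

#' Render a validation report as aligned text
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @export
print.validation_report <- function(x, ...) {
  lvs <- names(x$per_lv)
  cell <- function(metric, part)
    vapply(x$per_lv, function(e) e[[part]][[metric]], numeric(1))
  fmt <- function(v) formatC(v, format = "g", digits = 4, width = 10)
  cat("PLS-LS-SVM calibration report\n")
  cat(sprintf("%-24s%s\n", "NO. of LVs", paste(formatC(lvs, width = 10),
                                               collapse = "")))
  rows <- list(
    c("Prediction   r^2", "r_squared", "prediction"),
    c("             PRESS", "press", "prediction"),
    c("CV (LOO)     Q^2", "r_squared", "loo"),
    c("             PRESS", "press", "loo"),
    c("CV (LMO)     Q^2", "r_squared", "lmo"),
    c("             PRESS", "press", "lmo"))
  for (r in rows)
    cat(sprintf("%-24s%s\n", r[1],
                paste(fmt(cell(r[2], r[3])), collapse = "")))
  cat(sprintf("chosen LVs: %d\n", x$chosen_lv))
  if (!is.null(x$external))
    cat(sprintf("external validation: r^2 = %.4f, PRESS = %.4g (n = %d)\n",
                x$external$r_squared, x$external$press, x$external$n))
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}

report_to_list <- function(rep) {
  out <- list(per_lv = rep$per_lv, chosen_lv = rep$chosen_lv,
              gamma = rep$gamma, sigma2 = rep$sigma2)
  if (!is.null(rep$external)) out$external <- rep$external
  if (!is.null(rep$permutation)) {
    p <- rep$permutation
    out$permutation <- list(
      observed_r2 = p$observed_r2, permuted_r2 = p$permuted_r2,
      permuted_q2_loo = p$permuted_q2_loo,
      permuted_q2_lmo = p$permuted_q2_lmo,
      n_permutations = p$n_permutations, seed = p$seed,
      exceedance = p$exceedance)
  }
  out
}

#' Write a validation report to JSON
#'
#' Full double precision, stable key order; two runs of the same pipeline
#' produce byte-identical files.
#'
#' @param rep a `validation_report`.
#' @param path output path.
#' @export
write_report_json <- function(rep, path) {
  jsonlite::write_json(report_to_list(rep), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
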