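#' Fit a PLS1 regression by NIPALS
#'
#' Single-response partial least squares with the classical NIPALS recursion.
#' X and y are mean-centred; for each component `a`:
#' `w = X'y / ||X'y||`, `t = X w`, `p = X't / t't`, `q = y't / t't`, then
#' X is deflated by `t p'` and y by `q t`. For a single response the weight
#' step needs no inner iteration. Each weight vector is sign-fixed so its
#' largest-magnitude element is positive, making output reproducible across
#' linear-algebra backends. The rotation `R = W (P'W)^-1` maps centred
#' spectra directly to scores.
#'
#' @param X n x p numeric matrix (rows = samples).
#' @param y numeric response, length n, non-constant.
#' @param A number of latent variables, `A <= min(n - 1, p)`.
#' @return an object of class `pls_model`: `x_mean`, `y_mean`, `weights`
#'   (p x A), `loadings` (p x A), `y_loadings` (length A), `rotation`
#'   (p x A), `scores` (n x A training scores), `n_lv`.
#' @export
nipals_pls_fit <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("nipals_pls_fit: X and y dimension mismatch")
  if (A < 1L) stop("nipals_pls_fit: A must be >= 1")
  if (A > min(n - 1L, p))
    stop("nipals_pls_fit: A = ", A, " exceeds min(n - 1, p) = ",
         min(n - 1L, p))
  if (stats::sd(y) == 0) stop("nipals_pls_fit: y is constant")
  if (!all(is.finite(X))) stop("nipals_pls_fit: non-finite values in X")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xa <- sweep(X, 2L, x_mean)
  ya <- y - y_mean
  X0 <- Xa  # undeflated copy for scores via rotation

  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  tol <- .Machine$double.eps^0.5
  x_scale <- max(sqrt(sum(Xa^2)), 1)
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw <= tol * x_scale * max(abs(ya), 1))
      stop("nipals_pls_fit: no remaining X-y covariance at component ", a,
           "; achievable A is ", a - 1L)
    w <- w / nw
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tvec <- Xa %*% w
    tt <- sum(tvec^2)
    if (tt <= tol^2)
      stop("nipals_pls_fit: degenerate score at component ", a,
           "; achievable A is ", a - 1L)
    pl <- crossprod(Xa, tvec)[, 1L] / tt
    qa <- sum(ya * tvec) / tt
    Xa <- Xa - tcrossprod(tvec, pl)
    ya <- ya - qa * tvec[, 1L]
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  R <- W %*% solve(crossprod(P, W))
  scores <- X0 %*% R
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
                 y_loadings = q, rotation = R, scores = scores,
                 n_lv = as.integer(A)),
            class = "pls_model")
}

#' Project spectra onto the latent variables of a fitted PLS model
#'
#' @param m a `pls_model`.
#' @param X numeric matrix (or single row) with the training column count.
#' @return n x A score matrix `T = (X - x_mean) R`.
#' @export
pls_transform <- function(m, X) {
  stopifnot(inherits(m, "pls_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(m$x_mean))
    stop("pls_transform: expected ", length(m$x_mean), " columns, got ",
         ncol(X))
  sweep(X, 2L, m$x_mean) %*% m$rotation
}

#' Predict the response with the linear PLS regression alone
#'
#' `y_hat = y_mean + T q`; provided mainly for limit checks against the
#' hybrid model.
#'
#' @param m a `pls_model`.
#' @param X spectra matrix rows.
#' @return numeric predictions.
#' @export
pls_predict <- function(m, X) {
  drop(pls_transform(m, X) %*% m$y_loadings) + m$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variables over %d wavenumbers\n",
              x$n_lv, length(x$x_mean)))
  invisible(x)
}
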