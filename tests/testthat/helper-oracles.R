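# Independent reference implementations used only to check package output.
# They deliberately take different code paths from R/ (dist(), svd(),
# qr.solve(), explicit loops).

# Exhaustive greedy max-min Kennard-Stone oracle.
ks_oracle <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] > best_d) { best_d <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    rem <- setdiff(seq_len(n), sel)
    mins <- vapply(rem, function(r) min(D[r, sel]), numeric(1))
    sel <- c(sel, rem[which.max(mins)])
  }
  sel
}

# PLS1 via per-component SVD of the cross-covariance, with deflation.
pls1_svd_oracle <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  X0 <- Xc
  p <- ncol(X)
  W <- P <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    s <- crossprod(Xc, yc)
    w <- svd(s)$u[, 1L]
    if (w[which.max(abs(w))] < 0) w <- -w
    tv <- Xc %*% w
    tt <- drop(crossprod(tv))
    pl <- drop(crossprod(Xc, tv)) / tt
    qa <- drop(crossprod(yc, tv)) / tt
    Xc <- Xc - tcrossprod(tv, pl)
    yc <- yc - qa * drop(tv)
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  R <- W %*% solve(crossprod(P, W))
  scores <- X0 %*% R
  fitted <- ym + drop(scores %*% q)
  list(weights = W, loadings = P, y_loadings = q, scores = scores,
       fitted = fitted)
}

# OLS fitted values via the normal equations.
ols_fitted_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(X1 %*% solve(crossprod(X1), crossprod(X1, y)))
}

# LS-SVM dual via element-wise kernel loop and a generic solver.
lssvm_oracle <- function(T, y, gamma, sigma2) {
  T <- as.matrix(T); n <- nrow(T)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-sum((T[i, ] - T[j, ])^2) / (2 * sigma2))
  M <- matrix(0, n + 1L, n + 1L)
  M[1L, -1L] <- 1; M[-1L, 1L] <- 1
  M[-1L, -1L] <- K + diag(n) / gamma
  sol <- qr.solve(M, c(0, y))
  pred <- drop(K %*% sol[-1L]) + sol[1L]
  list(b = sol[1L], alpha = sol[-1L], fitted = pred)
}
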