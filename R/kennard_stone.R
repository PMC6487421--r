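#' Kennard-Stone calibration/test split
#'
#' Deterministic max-min selection on Euclidean distances between spectra:
#' the first two calibration samples are the pair at maximum distance; each
#' subsequent sample is the one whose minimum distance to the already-selected
#' set is largest. Ties are broken by the lowest original row index, so the
#' split needs no seed. Distances are computed on the (already SNV-processed)
#' intensity rows over the full wavenumber grid.
#'
#' @param m a [spectra_matrix()] (or plain numeric matrix).
#' @param n_cal number of calibration samples, `2 <= n_cal <= n`.
#' @return an object of class `split_indices`: list with `calibration`
#'   (integer indices in selection order) and `test` (the complement, in
#'   original order).
#' @export
kennard_stone <- function(m, n_cal) {
  X <- if (inherits(m, "spectra_matrix")) m$intensities else as.matrix(m)
  n <- nrow(X)
  if (n_cal < 2L || n_cal > n)
    stop("kennard_stone: n_cal must be in [2, ", n, "], got ", n_cal)
  if (!all(is.finite(X))) stop("kennard_stone: non-finite intensities")

  # full pairwise squared distances; desk-scale n makes O(n^2) memory fine
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0

  # initial pair: maximum distance, ties -> lexicographically smallest (i, j)
  best <- which(D2 == max(D2), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0L) best <- matrix(c(1L, 2L), 1L)  # all points identical
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1L, ])

  remaining <- setdiff(seq_len(n), sel)
  # min squared distance from each remaining point to the selected set
  mind2 <- pmin(D2[remaining, sel[1L]], D2[remaining, sel[2L]])
  while (length(sel) < n_cal) {
    pick_pos <- which.max(mind2)  # which.max takes the first (lowest index) tie
    pick <- remaining[pick_pos]
    sel <- c(sel, pick)
    remaining <- remaining[-pick_pos]
    mind2 <- mind2[-pick_pos]
    if (length(remaining)) mind2 <- pmin(mind2, D2[remaining, pick])
  }
  structure(list(calibration = sel, test = setdiff(seq_len(n), sel)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("split_indices: %d calibration / %d test\n",
              length(x$calibration), length(x$test)))
  invisible(x)
}

#' Apply a calibration/test split to paired spectra and responses
#'
#' @param m a [spectra_matrix()].
#' @param y a [response_vector()] aligned with `m`.
#' @param s a `split_indices` object from [kennard_stone()].
#' @return list with `cal_x`, `cal_y`, `test_x`, `test_y`; `test_x`/`test_y`
#'   are `NULL` when the test set is empty (a warning is emitted).
#' @export
apply_split <- function(m, y, s) {
  stopifnot(inherits(s, "split_indices"))
  check_paired(m, y)
  n <- nrow(m$intensities)
  all_idx <- sort(c(s$calibration, s$test))
  if (!identical(all_idx, seq_len(n)))
    stop("apply_split: split indices are not a partition of 1..", n)
  out <- list(
    cal_x = subset_samples(m, s$calibration),
    cal_y = y[s$calibration],
    test_x = NULL, test_y = NULL
  )
  if (length(s$test)) {
    out$test_x <- subset_samples(m, s$test)
    out$test_y <- y[s$test]
  } else {
    warning("apply_split: empty test set (n_cal = n)")
  }
  out
}
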