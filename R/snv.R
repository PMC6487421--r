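#' Standard normal variate transform of one spectrum
#'
#' Centres the spectrum by its own mean and scales by its own sample standard
#' deviation (n - 1 denominator over the p wavenumbers):
#' `SNV_i = (X_i - mean(X)) / sd(X)`. This removes any additive baseline
#' offset and multiplicative scatter factor exactly: SNV(a*x + b) = SNV(x)
#' for every a > 0 and any b.
#'
#' @param x numeric intensity vector, length >= 3, non-constant.
#' @param sample_id optional label used in error messages.
#' @return numeric vector with mean 0 and sample sd 1.
#' @examples
#' snv_row(c(1, 2, 3))  # -1 0 1
#' @export
snv_row <- function(x, sample_id = NULL) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("snv_row: need at least 3 wavenumbers")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    who <- if (is.null(sample_id)) "" else paste0(" (sample ", sample_id, ")")
    stop("snv_row: constant spectrum has zero variance", who,
         "; a flat spectrum indicates an upstream data problem")
  }
  (x - mean(x)) / s
}

#' Standard normal variate transform of a spectra matrix
#'
#' Applies [snv_row()] to every sample. Wavenumber axis and sample IDs pass
#' through unchanged; applied before any splitting or modelling so that
#' baseline fluctuations between samples are not mistaken for signal.
#'
#' @param m a [spectra_matrix()].
#' @return a `spectra_matrix` of the same shape, every row with mean 0 and
#'   sample sd 1.
#' @export
snv_matrix <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  X <- m$intensities
  mu <- rowMeans(X)
  sds <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    stop("snv_matrix: constant spectrum for sample(s): ",
         paste(m$sample_ids[bad], collapse = ", "))
  spectra_matrix((X - mu) / sds, m$wavenumbers, m$sample_ids)
}
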