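#' Construct a spectra matrix
#'
#' The central container of the package: an `n x p` matrix of absorbance
#' intensities with a wavenumber axis (cm^-1) and unique sample identifiers.
#' Samples are always rows internally; readers normalise orientation on the
#' way in. The wavenumber axis must be strictly monotone (descending is the
#' instrument-native order, 4000 -> 400 cm^-1) and is never reordered by any
#' transform in the package.
#'
#' @param intensities numeric matrix, `n` samples by `p` wavenumbers.
#' @param wavenumbers numeric vector of length `p`, strictly monotone.
#' @param sample_ids character vector of length `n`, unique. Defaults to
#'   existing rownames or `"S1" ... "Sn"`.
#' @return an object of class `spectra_matrix` with fields `intensities`,
#'   `wavenumbers`, `sample_ids`.
#' @examples
#' m <- spectra_matrix(matrix(rnorm(15), 3, 5), wavenumbers = seq(2000, 400, length.out = 5))
#' dim(m$intensities)
#' @export
spectra_matrix <- function(intensities, wavenumbers, sample_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (n < 1L) stop("spectra_matrix: need at least one sample (n >= 1)")
  if (p < 3L) stop("spectra_matrix: need at least 3 wavenumbers (p >= 3)")
  if (length(wavenumbers) != p)
    stop("spectra_matrix: wavenumbers length ", length(wavenumbers),
         " does not match ", p, " intensity columns")
  if (length(sample_ids) != n)
    stop("spectra_matrix: sample_ids length does not match row count")
  if (anyDuplicated(sample_ids))
    stop("spectra_matrix: sample_ids must be unique")
  if (!all(is.finite(intensities)))
    stop("spectra_matrix: intensities must be finite")
  if (!all(is.finite(wavenumbers)))
    stop("spectra_matrix: wavenumbers must be finite")
  d <- diff(wavenumbers)
  if (p >= 2L && !(all(d > 0) || all(d < 0)))
    stop("spectra_matrix: wavenumbers must be strictly monotone")
  dimnames(intensities) <- list(sample_ids, format_wavenumber(wavenumbers))
  structure(
    list(intensities = intensities, wavenumbers = wavenumbers,
         sample_ids = sample_ids),
    class = "spectra_matrix"
  )
}

format_wavenumber <- function(w) {
  # full precision, no scientific notation, stable across locales
  formatC(w, format = "g", digits = 15)
}

#' @export
print.spectra_matrix <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("spectra_matrix: %d samples x %d wavenumbers (%.6g-%.6g cm^-1)\n",
              nrow(x$intensities), ncol(x$intensities), rng[2], rng[1]))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$intensities)

#' Subset the samples of a spectra matrix
#'
#' @param m a [spectra_matrix()].
#' @param idx integer or logical row index.
#' @return a `spectra_matrix` containing the selected samples, in `idx` order.
#' @export
subset_samples <- function(m, idx) {
  stopifnot(inherits(m, "spectra_matrix"))
  spectra_matrix(m$intensities[idx, , drop = FALSE], m$wavenumbers,
                 m$sample_ids[idx])
}

#' Construct a response vector
#'
#' Per-sample reference concentrations (mg L^-1), aligned by position with a
#' paired [spectra_matrix()]. Stored as a named numeric vector of class
#' `response_vector`.
#'
#' @param values numeric vector of concentrations, finite and non-negative.
#' @param sample_ids character labels, same length as `values`.
#' @return a classed named numeric vector.
#' @export
response_vector <- function(values, sample_ids = NULL) {
  values <- as.numeric(values)
  if (is.null(sample_ids)) {
    sample_ids <- names(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(values))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(values))
    stop("response_vector: sample_ids length mismatch")
  if (anyDuplicated(sample_ids))
    stop("response_vector: sample_ids must be unique")
  if (!all(is.finite(values)))
    stop("response_vector: values must be finite")
  if (any(values < 0))
    stop("response_vector: concentrations must be >= 0")
  structure(stats::setNames(values, sample_ids), class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat(sprintf("response_vector: %d samples, range %.4g-%.4g mg/L\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' @export
`[.response_vector` <- function(x, i, ...) {
  response_vector(unclass(x)[i], names(unclass(x))[i])
}

check_paired <- function(m, y) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (length(y) != nrow(m$intensities))
    stop("spectra and response differ in sample count")
  if (!is.null(names(y)) && !identical(as.character(names(y)), m$sample_ids))
    stop("spectra and response sample_ids do not match in order")
  invisible(TRUE)
}

#' Read a spectra matrix from CSV
#'
#' Expected dialect: UTF-8, "." decimal separator; for `samples-as-rows` the
#' header row holds wavenumbers and the first column holds sample IDs (the
#' header of the ID column is ignored); `samples-as-columns` is the transpose.
#' Orientation is normalised to samples-as-rows internally.
#'
#' @param path CSV file path.
#' @param orientation `"samples-as-rows"` (default) or `"samples-as-columns"`.
#' @return a [spectra_matrix()].
#' @export
read_spectra_csv <- function(path,
                             orientation = c("samples-as-rows",
                                             "samples-as-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("read_spectra_csv: file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) < 2L || ncol(raw) < 2L)
    stop("read_spectra_csv: file too small to hold a spectra table: ", path)
  header <- as.character(raw[1L, -1L])
  ids <- as.character(raw[-1L, 1L])
  body <- as.matrix(raw[-1L, -1L, drop = FALSE])
  parsed <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(parsed) || anyNA(suppressWarnings(as.numeric(body)))) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "read_spectra_csv: non-numeric value %s at data row %d, column %d",
      dQuote(body[bad[1L], bad[2L]]), bad[1L], bad[2L]))
  }
  if (orientation == "samples-as-columns") {
    # header held sample IDs; first column held wavenumbers
    axis <- suppressWarnings(as.numeric(ids))
    if (anyNA(axis))
      stop("read_spectra_csv: non-numeric wavenumber in first column: ",
           dQuote(ids[which(is.na(axis))[1L]]))
    ids <- header
    parsed <- t(parsed)
  } else {
    axis <- suppressWarnings(as.numeric(header))
    if (anyNA(axis))
      stop("read_spectra_csv: non-numeric wavenumber in header: ",
           dQuote(header[which(is.na(axis))[1L]]))
  }
  if (anyDuplicated(axis))
    stop("read_spectra_csv: duplicate wavenumber in axis: ",
         axis[which(duplicated(axis))[1L]])
  spectra_matrix(parsed, axis, ids)
}

#' Write a spectra matrix to CSV
#'
#' Values are written with 17 significant digits so that a read/write/read
#' cycle is bit-stable for doubles.
#'
#' @param m a [spectra_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_spectra_csv <- function(m, path) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (!nzchar(path)) stop("write_spectra_csv: empty output path")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("write_spectra_csv: directory does not exist: ",
                    dirname(path))
  header <- paste(c("sample_id", num17(m$wavenumbers)), collapse = ",")
  rows <- vapply(seq_len(nrow(m$intensities)), function(i) {
    paste(c(m$sample_ids[i], num17(m$intensities[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

num17 <- function(x) {
  formatC(x, format = "g", digits = 17)
}

#' Read a response vector from CSV
#'
#' Two columns: `sample_id,value` with a header line.
#'
#' @param path CSV file path.
#' @return a [response_vector()].
#' @export
read_response_csv <- function(path) {
  if (!file.exists(path)) stop("read_response_csv: file not found: ", path)
  d <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(d) < 2L) stop("read_response_csv: need sample_id,value columns")
  vals <- suppressWarnings(as.numeric(d[[2L]]))
  if (anyNA(vals))
    stop("read_response_csv: non-numeric value at row ",
         which(is.na(vals))[1L])
  response_vector(vals, d[[1L]])
}

#' Write a response vector to CSV
#'
#' @param y a [response_vector()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_response_csv <- function(y, path) {
  stopifnot(inherits(y, "response_vector"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id,value",
               paste(names(y), num17(unclass(y)), sep = ",")), con)
  invisible(path)
}

#' Fit an ordinary least-squares straight-line calibration
#'
#' Used for the AAS reference channel: absorbance regressed on concentration.
#' The instrument response is assumed linear (Beer-Lambert regime), and the
#' fit quality is summarised by r-squared.
#'
#' @param x numeric concentrations (a [response_vector()] or plain vector).
#' @param y numeric absorbance readings, same length.
#' @return an object of class `linear_calibration` with `slope`, `intercept`,
#'   `r_squared`.
#' @examples
#' fit_linear_calibration(c(1, 2, 3), c(2, 4, 6))
#' @export
fit_linear_calibration <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("fit_linear_calibration: length mismatch")
  if (length(x) < 3L) stop("fit_linear_calibration: need n >= 3")
  if (max(x) == min(x))
    stop("fit_linear_calibration: degenerate design (constant x)")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc * xc)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(resid^2) / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2))),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("linear_calibration: a = %.6g * c + %.6g  (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
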