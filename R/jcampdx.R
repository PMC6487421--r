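#' Read a single spectrum from a JCAMP-DX file
#'
#' Supports the core labelled-data-record layout with an `##XYDATA=(X++(Y..Y))`
#' or `##XYPOINTS=(XY..XY)` table in plain AFFN numeric form. `##XFACTOR` and
#' `##YFACTOR` scalings are applied; compressed encodings (DIF/DUP/SQZ) are
#' rejected. The result is a one-row [spectra_matrix()].
#'
#' @param path JCAMP-DX file path.
#' @return a `spectra_matrix` with a single sample, its ID taken from
#'   `##TITLE` (or the file name when absent).
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path)) stop("read_jcampdx: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lab <- grepl("^##", lines)
  parse_label <- function(l) {
    m <- regmatches(l, regexec("^##([^=]*)=(.*)$", l))[[1]]
    if (length(m) < 3L) return(NULL)
    list(name = toupper(gsub("[ _-]", "", m[2])), value = trimws(m[3]))
  }
  labels <- list()
  data_start <- NA_integer_
  data_mode <- NA_character_
  for (i in which(lab)) {
    pl <- parse_label(lines[i])
    if (is.null(pl)) next
    if (pl$name %in% c("XYDATA", "XYPOINTS")) {
      data_start <- i
      data_mode <- pl$name
      data_form <- pl$value
    } else {
      labels[[pl$name]] <- pl$value
    }
  }
  if (is.na(data_start))
    stop("read_jcampdx: no ##XYDATA or ##XYPOINTS table in ", path)
  if (!("END" %in% names(labels)))
    stop("read_jcampdx: truncated file, missing ##END=")
  if (is.null(labels$XUNITS))
    stop("read_jcampdx: missing required label ##XUNITS")
  xf <- if (!is.null(labels$XFACTOR)) as.numeric(labels$XFACTOR) else 1
  yf <- if (!is.null(labels$YFACTOR)) as.numeric(labels$YFACTOR) else 1
  if (!is.finite(xf) || !is.finite(yf))
    stop("read_jcampdx: non-numeric XFACTOR/YFACTOR")

  j <- data_start + 1L
  tbl <- character(0)
  while (j <= length(lines) && !grepl("^##", lines[j])) {
    tbl <- c(tbl, lines[j])
    j <- j + 1L
  }
  tbl <- trimws(tbl)
  tbl <- tbl[nzchar(tbl)]
  if (!length(tbl)) stop("read_jcampdx: empty data table")
  if (any(grepl("[A-DF-Za-df-z%@]", tbl)))
    stop("read_jcampdx: compressed (SQZ/DIF/DUP) tables are not supported; ",
         "only plain AFFN numeric tables are read")

  toks <- lapply(strsplit(tbl, "[,;[:space:]]+"), function(v) {
    v <- v[nzchar(v)]
    suppressWarnings(as.numeric(v))
  })
  if (any(vapply(toks, anyNA, logical(1))))
    stop("read_jcampdx: non-numeric token in data table")

  if (data_mode == "XYPOINTS") {
    flat <- unlist(toks)
    if (length(flat) %% 2L != 0L)
      stop("read_jcampdx: odd token count in XYPOINTS table")
    x <- flat[seq(1L, length(flat), by = 2L)]
    y <- flat[seq(2L, length(flat), by = 2L)]
  } else {
    # X++(Y..Y): first token of each line is X of the first Y on that line;
    # subsequent Y values advance X by the implied grid step.
    xs <- ys <- list()
    for (k in seq_along(toks)) {
      v <- toks[[k]]
      if (length(v) < 2L)
        stop("read_jcampdx: XYDATA line with fewer than one (X, Y) pair")
      xs[[k]] <- v[1L]
      ys[[k]] <- v[-1L]
    }
    y <- unlist(ys)
    x_first <- unlist(xs)
    counts <- lengths(ys)
    if (length(x_first) > 1L) {
      # infer per-point step from consecutive line starts
      step <- (x_first[2L] - x_first[1L]) / counts[1L]
    } else {
      dx <- if (!is.null(labels$DELTAX)) as.numeric(labels$DELTAX) else NA
      step <- if (is.finite(dx)) dx / xf else 1
    }
    x <- unlist(lapply(seq_along(x_first), function(k) {
      x_first[k] + step * (seq_len(counts[k]) - 1L)
    }))
  }
  id <- if (!is.null(labels$TITLE) && nzchar(labels$TITLE)) labels$TITLE
        else basename(path)
  spectra_matrix(matrix(y * yf, nrow = 1L), x * xf, id)
}
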