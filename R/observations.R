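#' Validate a univariate count series
#'
#' Coerces `x` to an integer vector of non-negative counts, keeping `NA`
#' entries as missing observations. Missing values contribute a factor of the
#' identity matrix to the HMM likelihood, i.e. they are integrated out.
#'
#' @param x numeric vector of counts; `NA` marks a missing observation.
#' @return integer vector with the same length and missingness pattern.
#' @export
as_count_series <- function(x) {
  if (length(x) < 1L) stop("observation series must have length >= 1")
  x <- unclass(x)
  if (!is.numeric(x)) stop("observation series must be numeric")
  bad <- which(!is.na(x) & (x < 0 | x != round(x)))
  if (length(bad))
    stop("invalid observation at position ", bad[1L],
         ": counts must be non-negative integers (got ", x[bad[1L]], ")")
  as.integer(round(x))
}

#' Daily arousal counts from the Track Your Tinnitus app
#'
#' The embedded series of 87 successive daily values of the "arousal"
#' variable recorded by a single user of the Track Your Tinnitus (TYT)
#' mobile application. Higher values correspond to a higher degree of
#' excitement, lower values to a calmer emotional state. This short count
#' series is the package's worked example for two-state Poisson HMM fitting.
#'
#' @return integer vector of length 87.
#' @export
#' @examples
#' x <- tyt_arousal()
#' length(x)  # 87
tyt_arousal <- function() {
  as.integer(c(
    6, 5, 3, 6, 4, 3, 5, 6, 6, 6, 4, 6, 6, 4, 6, 6, 6, 6, 6, 4,
    6, 5, 6, 7, 6, 5, 5, 5, 7, 6, 5, 6, 5, 6, 6, 6, 5, 6, 7, 7,
    6, 7, 6, 6, 6, 6, 5, 7, 6, 1, 6, 0, 2, 1, 6, 7, 6, 6, 6, 5,
    5, 6, 6, 2, 5, 0, 1, 1, 1, 2, 3, 1, 3, 1, 3, 0, 1, 1, 1, 4,
    1, 4, 1, 2, 2, 2, 0))
}

#' Read a count series from a text file
#'
#' Accepts whitespace/newline-separated integers or a single-column CSV with
#' an optional header. Tokens matching one of the missing-value sentinels
#' (default `"NA"` and the empty field) become missing observations.
#'
#' @param path file path, or the fixture name `"tyt"` for the embedded
#'   [tyt_arousal()] series.
#' @param missing_sentinel character vector of tokens treated as missing.
#' @return integer count series with `NA` for missing values.
#' @export
read_counts <- function(path, missing_sentinel = c("NA", "")) {
  if (identical(path, "tyt")) return(tyt_arousal())
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub(",\\s*$", "", lines)         # tolerate trailing commas
  tokens <- character(0)
  pos <- list()
  for (ln in seq_along(lines)) {
    tk <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1L]]
    if (length(tk) == 0L && nzchar(trimws(lines[ln])) == FALSE && ln > 1L) {
      next
    }
    for (col in seq_along(tk)) {
      tokens <- c(tokens, tk[col])
      pos[[length(pos) + 1L]] <- c(ln, col)
    }
  }
  # optional single header token on the first line of a one-column file
  if (length(tokens) && !tokens[1L] %in% missing_sentinel &&
      suppressWarnings(is.na(as.numeric(tokens[1L]))) &&
      pos[[1L]][1L] == 1L && (length(pos) < 2L || pos[[2L]][1L] > 1L)) {
    tokens <- tokens[-1L]
    pos <- pos[-1L]
  }
  out <- rep(NA_integer_, length(tokens))
  for (i in seq_along(tokens)) {
    tk <- tokens[i]
    if (tk %in% missing_sentinel) next
    v <- suppressWarnings(as.numeric(tk))
    if (is.na(v) || v < 0 || v != round(v))
      stop("parse error at line ", pos[[i]][1L], ", field ", pos[[i]][2L],
           ": expected a non-negative integer, got \"", tk, "\"")
    out[i] <- as.integer(v)
  }
  if (length(out) == 0L) stop("no observations found in ", path)
  out
}
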