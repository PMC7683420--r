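#' Construct a single spectrum
#'
#' A spectrum is a vector of reflectance values on an explicit wavelength
#' grid (nm). Used for per-kernel mean spectra and their smoothed /
#' normalized derivatives.
#'
#' @param values numeric vector of reflectance values, one per channel.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, same length as `values`.
#' @return an object of class `"spectrum"`: a list with elements `values`
#'   and `wavelengths`.
#' @export
as_spectrum <- function(values, wavelengths) {
  values <- as.numeric(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(values) != length(wavelengths))
    abort_validation("values and wavelengths differ in length (",
                     length(values), " vs ", length(wavelengths), ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    abort_validation("wavelengths must be strictly increasing")
  check_finite(values, "spectrum values")
  structure(list(values = values, wavelengths = wavelengths),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", length(x$values), " channels, ",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)), " nm\n",
      sep = "")
  invisible(x)
}

#' Moving-average smoothing of a spectrum
#'
#' Centered mean filter of odd window size (default 5), the standard light
#' smoothing applied to per-kernel mean spectra before normalization.
#' Edges are handled by reflect padding (the first/last `window %/% 2`
#' values are mirrored, excluding the edge value itself), which keeps
#' endpoint bias small.
#'
#' @param s a `"spectrum"` object (see [as_spectrum()]).
#' @param window odd integer window size, `1 <= window <=` number of channels.
#' @return a smoothed `"spectrum"` on the same wavelength grid.
#' @export
smooth_spectrum <- function(s, window = 5L) {
  stopifnot(inherits(s, "spectrum"))
  window <- as.integer(window)
  n <- length(s$values)
  if (window < 1L || window %% 2L == 0L)
    abort_validation("window must be an odd positive integer, got ", window)
  if (window > n)
    abort_validation("window (", window, ") exceeds channel count (", n, ")")
  if (window == 1L) return(s)
  p <- window %/% 2L
  x <- s$values
  padded <- c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
  sm <- as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))
  as_spectrum(sm[(p + 1L):(p + n)], s$wavelengths)
}

#' Average normalization of a spectrum
#'
#' Divides a spectrum by its own arithmetic mean so the output has mean
#' exactly 1. Together with [smooth_spectrum()] this is the preprocessing
#' applied to every kernel mean spectrum; it removes multiplicative
#' scatter differences between kernels.
#'
#' @param s a `"spectrum"` object.
#' @return the normalized `"spectrum"`; `mean(values)` is 1 to within 1e-9.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- mean(s$values)
  if (abs(m) < 1e-12)
    abort_validation("cannot normalize a zero-mean spectrum")
  as_spectrum(s$values / m, s$wavelengths)
}

#' Assemble preprocessed spectra into a labelled matrix
#'
#' @param spectra list of `"spectrum"` objects sharing one wavelength grid.
#' @param labels integer class labels in `{0..q-1}`, one per spectrum.
#' @param splits optional character vector (`"cal"`, `"val"` or `"pre"`)
#'   assigning each sample to the calibration, validation or prediction set.
#' @return a `"spectra_matrix"`: list with `X` (N x Ch numeric matrix),
#'   `labels` (integer), `wavelengths`, and `splits` (or `NULL`).
#' @export
build_spectra_matrix <- function(spectra, labels, splits = NULL) {
  if (length(spectra) != length(labels))
    abort_validation("spectra and labels differ in length")
  if (!length(spectra)) abort_validation("no spectra given")
  wl <- spectra[[1L]]$wavelengths
  for (s in spectra) {
    if (!inherits(s, "spectrum")) abort_validation("all elements must be spectra")
    if (length(s$wavelengths) != length(wl) || any(s$wavelengths != wl))
      abort_validation("spectra do not share one wavelength grid")
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "values"))
  spectra_matrix(X, labels, wl, splits)
}

#' Low-level spectra-matrix constructor
#'
#' @param X numeric N x Ch matrix, rows = samples.
#' @param labels integer labels in `{0..q-1}`.
#' @param wavelengths length-Ch numeric vector (nm).
#' @param splits optional per-sample split assignment.
#' @export
spectra_matrix <- function(X, labels, wavelengths, splits = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.integer(labels)
  if (nrow(X) != length(labels))
    abort_validation("nrow(X) != length(labels)")
  if (ncol(X) != length(wavelengths))
    abort_validation("ncol(X) != length(wavelengths)")
  if (any(labels < 0L)) abort_validation("labels must be >= 0")
  check_finite(X, "spectra matrix")
  if (!is.null(splits)) {
    splits <- as.character(splits)
    if (length(splits) != nrow(X))
      abort_validation("splits length mismatch")
    bad <- setdiff(unique(splits), c("cal", "val", "pre"))
    if (length(bad)) abort_validation("unknown split name: ", bad[1L])
  }
  structure(list(X = X, labels = labels,
                 wavelengths = as.numeric(wavelengths), splits = splits),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat("<spectra_matrix> ", nrow(x$X), " samples x ", ncol(x$X), " channels, ",
      length(unique(x$labels)), " classes", sep = "")
  if (!is.null(x$splits)) {
    tb <- table(x$splits)
    cat(" [", paste(names(tb), tb, sep = "=", collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Subset a spectra matrix by split, rows or channels
#'
#' @param sm a `"spectra_matrix"`.
#' @param split one of `"cal"`, `"val"`, `"pre"` (requires `sm$splits`).
#' @param rows integer row indices.
#' @param channels integer channel indices (1-based).
#' @export
sm_subset <- function(sm, split = NULL, rows = NULL, channels = NULL) {
  stopifnot(inherits(sm, "spectra_matrix"))
  idx <- seq_len(nrow(sm$X))
  if (!is.null(split)) {
    if (is.null(sm$splits)) abort_validation("spectra matrix has no splits")
    idx <- idx[sm$splits[idx] %in% split]
  }
  if (!is.null(rows)) idx <- intersect(idx, rows)
  ch <- channels %||% seq_len(ncol(sm$X))
  spectra_matrix(sm$X[idx, ch, drop = FALSE], sm$labels[idx],
                 sm$wavelengths[ch],
                 if (is.null(sm$splits)) NULL else sm$splits[idx])
}

#' Write / read a spectra matrix as delimited text
#'
#' Format: one header row of wavelengths plus a final `label` column, then
#' one row per sample with the integer class label last.
#'
#' @param sm a `"spectra_matrix"`.
#' @param path file path.
#' @param sep field separator (default comma).
#' @export
write_spectra <- function(sm, path, sep = ",") {
  stopifnot(inherits(sm, "spectra_matrix"))
  header <- c(format(sm$wavelengths, trim = TRUE, digits = 15), "label")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  body <- cbind(format(sm$X, trim = TRUE, digits = 17), sm$labels)
  writeLines(apply(body, 1L, paste, collapse = sep), con)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, sep = ",") {
  if (!file.exists(path)) abort_format("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "")
  if (ncol(tab) < 2L || names(tab)[ncol(tab)] != "label")
    abort_format("last column of a spectra table must be 'label'")
  wl <- as.numeric(names(tab)[-ncol(tab)])
  if (anyNA(wl)) abort_format("header wavelengths are not numeric")
  spectra_matrix(as.matrix(tab[, -ncol(tab), drop = FALSE]),
                 tab[[ncol(tab)]], wl)
}
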