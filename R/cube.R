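#' Hyperspectral cube containers
#'
#' A raw cube holds uncalibrated sensor intensities as a rows x cols x bands
#' array with an explicit wavelength axis (nm). A reflectance cube holds the
#' same geometry after dark/white calibration.
#'
#' @param data numeric 3-D array, dim = c(rows, cols, bands).
#' @param wavelengths strictly increasing numeric vector, length = bands.
#' @return an object of class `"raw_cube"` / `"reflectance_cube"`.
#' @export
raw_cube <- function(data, wavelengths) {
  new_cube(data, wavelengths, "raw_cube")
}

#' @rdname raw_cube
#' @export
reflectance_cube <- function(data, wavelengths) {
  new_cube(data, wavelengths, "reflectance_cube")
}

new_cube <- function(data, wavelengths, class) {
  if (length(dim(data)) != 3L)
    abort_validation("cube data must be a 3-D array (rows, cols, bands)")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3L] != length(wavelengths))
    abort_validation("band count (", dim(data)[3L],
                     ") != wavelength count (", length(wavelengths), ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    abort_validation("wavelengths must be strictly increasing")
  check_finite(data, "cube data")
  structure(list(data = data, wavelengths = wavelengths), class = class)
}

#' @export
print.raw_cube <- function(x, ...) print_cube(x, "raw_cube")
#' @export
print.reflectance_cube <- function(x, ...) print_cube(x, "reflectance_cube")

print_cube <- function(x, what) {
  d <- dim(x$data)
  cat("<", what, "> ", d[1L], " x ", d[2L], " px, ", d[3L], " bands (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)), " nm)\n",
      sep = "")
  invisible(x)
}

#' White/dark reference frames for reflectance calibration
#'
#' Each reference may be a scalar, a per-band vector (length = bands) or a
#' full array matching the cube; it is broadcast against the cube data.
#'
#' @param white white-tile reference intensities.
#' @param dark lens-capped dark reference intensities.
#' @export
reference_frames <- function(white, dark) {
  structure(list(white = white, dark = dark), class = "reference_frames")
}

broadcast_ref <- function(ref, dims, what) {
  if (is.null(dim(ref))) {
    if (length(ref) == 1L) return(array(ref, dims))
    if (length(ref) == dims[3L])
      return(aperm(array(ref, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
    abort_validation(what, " reference has length ", length(ref),
                     "; expected 1 or the band count ", dims[3L])
  }
  if (length(dim(ref)) == 3L && all(dim(ref) == dims)) return(ref)
  abort_validation(what, " reference shape is not broadcastable to the cube")
}

#' Dark/white reflectance calibration
#'
#' Converts raw intensities to reflectance via
#' `(raw - dark) / (white - dark)`, elementwise. Elements where
#' `|white - dark|` falls below `guard_eps` cannot be calibrated; they are
#' either set to `NA` with a warning (`degenerate = "mask"`, the default) or
#' raise an error (`degenerate = "error"`).
#'
#' @param raw a `"raw_cube"`.
#' @param refs a `"reference_frames"` object.
#' @param guard_eps smallest allowed `|white - dark|` denominator.
#' @param degenerate `"mask"` or `"error"`.
#' @return a `"reflectance_cube"` with the wavelength axis preserved.
#' @export
calibrate <- function(raw, refs, guard_eps = 1e-12,
                      degenerate = c("mask", "error")) {
  stopifnot(inherits(raw, "raw_cube"), inherits(refs, "reference_frames"))
  degenerate <- match.arg(degenerate)
  dims <- dim(raw$data)
  white <- broadcast_ref(refs$white, dims, "white")
  dark <- broadcast_ref(refs$dark, dims, "dark")
  denom <- white - dark
  bad <- abs(denom) < guard_eps
  if (any(bad)) {
    if (degenerate == "error")
      abort_validation(sum(bad), " cube element(s) have |white - dark| < ",
                       guard_eps)
    warning(sum(bad), " element(s) with degenerate white-dark reference ",
            "masked as NA", call. = FALSE)
    denom[bad] <- 1
  }
  out <- (raw$data - dark) / denom
  if (any(bad)) out[bad] <- NA_real_
  cube <- structure(list(data = out, wavelengths = raw$wavelengths),
                    class = "reflectance_cube")
  cube
}

#' Crop a cube to a wavelength window
#'
#' Retains exactly the bands with `lo_nm <= wavelength <= hi_nm` (inclusive
#' at both ends). The defaults keep 975-1645 nm, the informative window of a
#' typical NIR kernel scan after discarding the noisy spectral extremes.
#'
#' @param cube a `"reflectance_cube"` (or `"raw_cube"`).
#' @param lo_nm,hi_nm wavelength window in nm.
#' @export
crop_bands <- function(cube, lo_nm = 975, hi_nm = 1645) {
  stopifnot(inherits(cube, c("raw_cube", "reflectance_cube")))
  keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
  if (!length(keep))
    abort_validation("no bands inside [", lo_nm, ", ", hi_nm, "] nm")
  new_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
           class(cube)[1L])
}

# ---- ENVI header + binary I/O ------------------------------------------

# ENVI data type codes supported: 4 = float32, 5 = float64
envi_sizes <- c("4" = 4L, "5" = 8L)

#' Read a hyperspectral cube from an ENVI header + binary pair
#'
#' Supports BSQ, BIL and BIP interleaves and float32/float64 data
#' (little/big endian). The header must declare `samples`, `lines`,
#' `bands`, `data type`, `interleave` and a `wavelength` list whose length
#' equals the band count.
#'
#' @param path path to the `.hdr` header file (the binary file is the same
#'   path without the `.hdr` extension, or with `.dat` appended).
#' @param format only `"envi"` is supported.
#' @return a `"raw_cube"` with data arranged rows (= lines) x cols
#'   (= samples) x bands.
#' @export
read_cube <- function(path, format = "envi") {
  format <- match.arg(format, "envi")
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr_path)) abort_format("ENVI header not found: ", hdr_path)
  hdr <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[k]])) abort_format("ENVI header misses field '", k, "'")
  if (is.null(hdr$wavelength))
    abort_format("ENVI header misses the required 'wavelength' list")
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1L]])
  if (anyNA(wl)) abort_format("non-numeric wavelength entries")
  if (length(wl) != nb)
    abort_validation("header declares ", nb, " bands but ", length(wl),
                     " wavelengths")
  dt <- as.character(as.integer(hdr$`data type`))
  if (!dt %in% names(envi_sizes))
    abort_format("unsupported ENVI data type ", dt, " (need 4 or 5)")
  endian <- if (identical(as.integer(hdr$`byte order` %||% 0), 1L))
    "big" else "little"
  bin_path <- sub("\\.hdr$", "", hdr_path)
  if (!file.exists(bin_path)) bin_path <- paste0(bin_path, ".dat")
  if (!file.exists(bin_path)) abort_format("ENVI binary not found for ", hdr_path)
  n <- ns * nl * nb
  raw <- readBin(bin_path, "double", n = n, size = envi_sizes[dt],
                 endian = endian)
  if (length(raw) != n)
    abort_format("ENVI binary holds ", length(raw), " values; expected ", n)
  interleave <- tolower(trimws(hdr$interleave))
  # fastest-varying dimension first in each read layout
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, c(nb, ns, nl)), c(3L, 2L, 1L)),
    abort_format("unknown interleave '", interleave, "'"))
  raw_cube(arr, wl)
}

#' Write a cube as an ENVI header + binary pair
#'
#' @param cube a `"raw_cube"` or `"reflectance_cube"`.
#' @param path output path; `.hdr` is appended for the header.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type 4 (float32) or 5 (float64, default: lossless for R
#'   doubles).
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, c("raw_cube", "reflectance_cube")))
  interleave <- match.arg(interleave)
  dt <- as.character(as.integer(data_type))
  if (!dt %in% names(envi_sizes)) abort_format("data_type must be 4 or 5")
  d <- dim(cube$data)  # rows(lines), cols(samples), bands
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bip = aperm(cube$data, c(3L, 2L, 1L)))
  writeBin(as.vector(arr), path, size = envi_sizes[dt], endian = "little")
  hdr <- c("ENVI",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", dt),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength = {\n ",
                  paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                        collapse = ",\n "),
                  "\n}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[1L]))
    abort_format("not an ENVI header (missing ENVI magic): ", hdr_path)
  txt <- paste(lines[-1L], collapse = "\n")
  out <- list()
  pos <- 1L
  # key = value, where value may be a {...} block spanning lines
  pat <- "(?s)([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) abort_format("empty ENVI header: ", hdr_path)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    val <- gsub("[{}]", "", val)
    val <- gsub("\\s+", " ", trimws(val))
    out[[key]] <- val
  }
  out
}
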