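#' Segment kernels in a single-band pseudo-image
#'
#' Reproduces the standard plate-segmentation chain for kernels imaged on a
#' low-reflectance background: Otsu threshold on one band's pseudo-image,
#' morphological opening (erosion then dilation) with a disk structuring
#' element, connected-component labeling, and an area filter. Regions are
#' returned sorted by centroid (row, then column).
#'
#' @param cube a `"reflectance_cube"`.
#' @param band 1-based band index of the pseudo-image (default 20, the
#'   customary low-noise display band).
#' @param min_area discard components with fewer pixels than this.
#' @param disk_diameter diameter (px) of the disk structuring element used
#'   for the opening.
#' @param connectivity 8 (default) or 4 for component labeling.
#' @return list of `"kernel_region"` objects, each with `pixel_mask`
#'   (logical rows x cols matrix), `centroid` (row, col), `bbox`
#'   (row_min, row_max, col_min, col_max; 1-based inclusive) and `area`.
#' @export
segment_kernels <- function(cube, band = 20L, min_area = 10L,
                            disk_diameter = 5L, connectivity = 8L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  nb <- dim(cube$data)[3L]
  band <- as.integer(band)
  if (band < 1L || band > nb)
    abort_validation("band ", band, " outside 1..", nb)
  img <- cube$data[, , band]
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant pseudo-image: Otsu threshold is degenerate; ",
            "no regions returned", call. = FALSE)
    return(list())
  }
  th <- EBImage::otsu(img, range = rng)
  mask <- img > th
  if (disk_diameter >= 2L) {
    brush <- EBImage::makeBrush(as.integer(disk_diameter), shape = "disc")
    mask <- EBImage::dilate(EBImage::erode(mask * 1, brush), brush) > 0.5
  }
  labels <- label_components(mask, connectivity = connectivity)
  k <- max(labels)
  if (k == 0L) return(list())
  regions <- vector("list", k)
  for (i in seq_len(k)) {
    px <- which(labels == i, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    pm <- labels == i
    regions[[i]] <- structure(list(
      pixel_mask = pm,
      centroid = c(row = mean(px[, 1L]), col = mean(px[, 2L])),
      bbox = c(row_min = min(px[, 1L]), row_max = max(px[, 1L]),
               col_min = min(px[, 2L]), col_max = max(px[, 2L])),
      area = nrow(px)), class = "kernel_region")
  }
  regions <- Filter(Negate(is.null), regions)
  ord <- order(vapply(regions, function(r) r$centroid[1L], 0),
               vapply(regions, function(r) r$centroid[2L], 0))
  regions[ord]
}

#' @export
print.kernel_region <- function(x, ...) {
  cat(sprintf("<kernel_region> area %d px, centroid (%.1f, %.1f)\n",
              x$area, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

#' Connected-component labeling with selectable connectivity
#'
#' Labels the foreground of a logical mask using 4- or 8-neighbor
#' adjacency. Components are numbered 1..K in first-pixel (column-major)
#' order; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    abort_validation("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(fg)) return(out)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # renumber components by first (column-major) foreground pixel
  first <- tapply(seq_along(fg), comp, min)
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  out[fg] <- renum[comp]
  out
}

#' Extract a fixed-size square kernel cube around a region
#'
#' Cuts a `side` x `side` spatial window centered on the rounded region
#' centroid. Near an image edge the window is shifted (never shrunk) so it
#' stays fully inside the cube.
#'
#' @param cube a `"reflectance_cube"`.
#' @param region a `"kernel_region"` from [segment_kernels()].
#' @param side window side length in pixels (default 30).
#' @return a `"kernel_cube"`: list with `data` (side x side x bands),
#'   `origin` (1-based row, col of the window's top-left pixel in the
#'   parent cube) and `wavelengths`.
#' @export
extract_kernel_cube <- function(cube, region, side = 30L) {
  stopifnot(inherits(cube, "reflectance_cube"),
            inherits(region, "kernel_region"))
  side <- as.integer(side)
  if (side < 1L) abort_validation("side must be >= 1")
  d <- dim(cube$data)
  if (d[1L] < side || d[2L] < side)
    abort_validation("cube (", d[1L], " x ", d[2L],
                     ") is smaller than the ", side, "-px window")
  start <- as.integer(round(region$centroid)) - side %/% 2L
  start <- pmin(pmax(start, 1L), as.integer(c(d[1L], d[2L])) - side + 1L)
  names(start) <- c("row", "col")
  rows <- start[1L]:(start[1L] + side - 1L)
  cols <- start[2L]:(start[2L] + side - 1L)
  structure(list(data = cube$data[rows, cols, , drop = FALSE],
                 origin = start,
                 wavelengths = cube$wavelengths),
            class = "kernel_cube")
}

#' Per-band mean spectrum of a kernel cube
#'
#' Averages every spatial pixel of the extracted square window per band
#' (the default), or only the pixels of an optional foreground mask.
#'
#' @param kc a `"kernel_cube"`.
#' @param mask optional logical side x side matrix selecting pixels.
#' @return a `"spectrum"`.
#' @export
kernel_mean_spectrum <- function(kc, mask = NULL) {
  stopifnot(inherits(kc, "kernel_cube"))
  d <- dim(kc$data)
  flat <- matrix(kc$data, d[1L] * d[2L], d[3L])
  if (!is.null(mask)) {
    if (!is.logical(mask) || any(dim(mask) != d[1:2]))
      abort_validation("mask must be a logical ", d[1L], " x ", d[2L],
                       " matrix")
    if (!any(mask)) abort_validation("mask selects no pixels")
    flat <- flat[as.vector(mask), , drop = FALSE]
  }
  as_spectrum(colMeans(flat), kc$wavelengths)
}
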