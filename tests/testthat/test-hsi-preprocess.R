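test_that("calibration satisfies the reflectance identities", {
  set.seed(1)
  dims <- c(6, 7, 4)
  wl <- c(980, 1100, 1300, 1600)
  white <- array(runif(prod(dims), 800, 1000), dims)
  dark <- array(runif(prod(dims), 50, 120), dims)
  refs <- reference_frames(white, dark)

  expect_equal(calibrate(raw_cube(white, wl), refs)$data,
               array(1, dims))
  expect_equal(calibrate(raw_cube(dark, wl), refs)$data,
               array(0, dims))
  mid <- calibrate(raw_cube((white + dark) / 2, wl), refs)
  expect_equal(mid$data, array(0.5, dims))
  expect_identical(mid$wavelengths, wl)

  # strictly increasing in the raw signal at fixed references
  bump <- dark + 0.25 * (white - dark)
  expect_true(all(calibrate(raw_cube(bump, wl), refs)$data <
                    calibrate(raw_cube((white + dark) / 2, wl), refs)$data))
})

test_that("calibration supports per-band references and flags degenerate pixels", {
  wl <- c(1000, 1200)
  raw <- raw_cube(array(550, c(2, 2, 2)), wl)
  out <- calibrate(raw, reference_frames(white = c(1000, 1100),
                                         dark = c(100, 100)))
  expect_equal(out$data[, , 1], matrix(0.5, 2, 2))
  expect_equal(out$data[, , 2], matrix(0.45, 2, 2))

  white <- array(1000, c(2, 2, 2)); white[1, 1, 1] <- 100
  expect_warning(
    masked <- calibrate(raw, reference_frames(white, 100)),
    "degenerate")
  expect_true(is.na(masked$data[1, 1, 1]))
  expect_false(anyNA(masked$data[-1]))
  expect_error(
    calibrate(raw, reference_frames(white, 100), degenerate = "error"),
    class = "wavesel_validation_error")
})

test_that("crop_bands keeps exactly the bands inside the inclusive window", {
  cube <- reflectance_cube(array(0.5, c(2, 2, 3)), c(900, 1000, 1700))
  out <- crop_bands(cube)
  expect_identical(out$wavelengths, 1000)
  one <- crop_bands(cube, lo_nm = 1000, hi_nm = 1000)
  expect_identical(one$wavelengths, 1000)
  expect_error(crop_bands(cube, lo_nm = 1701, hi_nm = 1800),
               class = "wavesel_validation_error")

  # 256 evenly spaced bands over 874-1734 nm: count from the inclusive rule
  wl256 <- seq(874, 1734, length.out = 256)
  cube256 <- reflectance_cube(array(1, c(2, 2, 256)), wl256)
  expected_n <- sum(wl256 >= 975 & wl256 <= 1645)
  expect_identical(length(crop_bands(cube256)$wavelengths), expected_n)
})

test_that("segmentation recovers planted disks and filters small components", {
  centers <- rbind(c(15, 15), c(15, 45), c(45, 30))
  cube <- disk_cube(centers)
  regions <- segment_kernels(cube, band = 1, min_area = 10)
  expect_length(regions, 3)
  found <- t(vapply(regions, function(r) unname(r$centroid), numeric(2)))
  ord <- order(centers[, 1], centers[, 2])
  expect_true(all(abs(found - centers[ord, ]) <= 1))
  expect_true(all(vapply(regions, function(r) r$area > 0, TRUE)))
  # pairwise disjoint masks
  expect_true(max(Reduce(`+`, lapply(regions, `[[`, "pixel_mask"))) == 1)

  # a single bright pixel survives neither the opening nor the area filter
  lone <- array(0.05, c(40, 40, 2)); lone[20, 20, ] <- 0.9
  expect_length(
    segment_kernels(reflectance_cube(lone, c(1000, 1001)),
                    band = 1, min_area = 5), 0)

  # constant image: degenerate Otsu -> empty with warning
  flat <- reflectance_cube(array(0.3, c(10, 10, 2)), c(1000, 1001))
  expect_warning(out <- segment_kernels(flat, band = 1), "degenerate")
  expect_length(out, 0)
})

test_that("segmentation recovers the planted count for K in {1, 5, 25}", {
  for (grid in list(c(1, 1), c(1, 5), c(5, 5))) {
    spec <- standard_fixtures()$cube_small
    cube_gen <- make_synthetic_cube(spec, grid = grid)
    refl <- calibrate(cube_gen$raw, cube_gen$refs)
    regions <- segment_kernels(refl, band = 20, min_area = 10)
    expect_length(regions, prod(grid))
    found <- t(vapply(regions, function(r) unname(r$centroid), numeric(2)))
    planted <- cube_gen$truth$centers
    ord <- order(planted[, 1], planted[, 2])
    expect_true(all(abs(found - planted[ord, , drop = FALSE]) <= 1))
  }
})

test_that("connected-component labeling honors connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  expect_identical(max(label_components(m, 8)), 1L)
  expect_identical(max(label_components(m, 4)), 2L)

  # 4-connectivity agrees with EBImage::bwlabel on a random mask
  set.seed(5)
  rnd <- matrix(runif(400) > 0.6, 20, 20)
  mine <- label_components(rnd, 4)
  ref <- EBImage::bwlabel(rnd)
  expect_identical(max(mine), as.integer(max(ref)))
  # identical partition: label pairs must biject
  expect_identical(length(unique(paste(mine[rnd], ref[rnd]))),
                   length(unique(mine[rnd])))
})

test_that("kernel-cube extraction centers the window and clamps at edges", {
  arr <- array(rep(runif(5), each = 100 * 100), c(100, 100, 5))
  cube <- reflectance_cube(arr, 1:5 * 100 + 900)
  mid <- structure(list(pixel_mask = NULL, centroid = c(row = 51, col = 51),
                        bbox = NULL, area = 10L), class = "kernel_region")
  kc <- extract_kernel_cube(cube, mid, side = 30)
  expect_identical(kc$origin, c(row = 36L, col = 36L))
  expect_identical(dim(kc$data), c(30L, 30L, 5L))
  # spatially uniform cube: every window pixel equals the uniform spectrum
  expect_equal(max(apply(kc$data, 3, function(s) diff(range(s)))), 0)

  edge <- structure(list(pixel_mask = NULL, centroid = c(row = 2, col = 2),
                         bbox = NULL, area = 10L), class = "kernel_region")
  kc2 <- extract_kernel_cube(cube, edge, side = 30)
  expect_identical(kc2$origin, c(row = 1L, col = 1L))

  small <- reflectance_cube(array(1, c(10, 10, 2)), c(1000, 1100))
  expect_error(extract_kernel_cube(small, mid, side = 30),
               class = "wavesel_validation_error")
})

test_that("kernel mean spectrum equals the brute-force pixel loop", {
  set.seed(7)
  kc <- structure(list(data = array(runif(4 * 4 * 6), c(4, 4, 6)),
                       origin = c(row = 1L, col = 1L),
                       wavelengths = seq(1000, 1500, length.out = 6)),
                  class = "kernel_cube")
  expect_equal(kernel_mean_spectrum(kc)$values, brute_mean_spectrum(kc),
               tolerance = 1e-12)
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(kernel_mean_spectrum(kc, mask)$values,
               brute_mean_spectrum(kc, mask), tolerance = 1e-12)

  # uniform cube returns the pixel spectrum; two-pixel toy averages
  u <- structure(list(data = array(rep(1:6, each = 4), c(2, 2, 6)),
                      origin = c(row = 1L, col = 1L), wavelengths = 1:6),
                 class = "kernel_cube")
  expect_equal(kernel_mean_spectrum(u)$values, as.numeric(1:6))
  two <- structure(list(data = array(c(0, 2), c(1, 2, 3)),
                        origin = c(row = 1L, col = 1L), wavelengths = 1:3),
                   class = "kernel_cube")
  expect_equal(kernel_mean_spectrum(two)$values, c(1, 1, 1))
  expect_error(kernel_mean_spectrum(kc, matrix(FALSE, 4, 4)),
               class = "wavesel_validation_error")
})

test_that("mean-filter smoothing follows moving-average arithmetic", {
  wl <- seq_len(11)
  const <- as_spectrum(rep(3, 11), wl)
  expect_equal(smooth_spectrum(const)$values, rep(3, 11))

  imp <- as_spectrum(c(rep(0, 5), 1, rep(0, 5)), wl)
  sm <- smooth_spectrum(imp, 5)
  expect_equal(sm$values[4:8], rep(0.2, 5))
  expect_equal(sum(sm$values), 1)

  ramp <- as_spectrum(as.numeric(1:11), wl)
  expect_equal(smooth_spectrum(ramp, 5)$values[3:9], as.numeric(3:9))

  expect_error(smooth_spectrum(const, 4),
               class = "wavesel_validation_error")
})

test_that("average normalization gives unit mean and the chain is scale invariant", {
  expect_equal(normalize_spectrum(as_spectrum(c(2, 2, 2), 1:3))$values,
               c(1, 1, 1))
  expect_equal(normalize_spectrum(as_spectrum(c(1, 3), 1:2))$values,
               c(0.5, 1.5))
  expect_error(normalize_spectrum(as_spectrum(c(-1, 1), 1:2)),
               class = "wavesel_validation_error")

  set.seed(11)
  for (i in 1:1000) {
    s <- as_spectrum(runif(20, 0.1, 2), 1:20)
    expect_lt(abs(mean(normalize_spectrum(s)$values) - 1), 1e-9)
  }

  s <- as_spectrum(runif(30, 0.5, 1.5), 1:30)
  chain <- function(x) normalize_spectrum(smooth_spectrum(x, 5))$values
  for (c_scale in c(0.01, 3, 250))
    expect_equal(chain(as_spectrum(s$values * c_scale, 1:30)), chain(s))
})

test_that("spectra matrices assemble, validate and round-trip as text", {
  wl <- seq(975, 1645, length.out = 200)
  sp <- lapply(1:3, function(i) as_spectrum(runif(200, 0.5, 1.5), wl))
  sm <- build_spectra_matrix(sp, c(0L, 1L, 2L))
  expect_identical(dim(sm$X), c(3L, 200L))

  other <- as_spectrum(runif(200), wl + 1)
  expect_error(build_spectra_matrix(c(sp, list(other)), 0:3),
               class = "wavesel_validation_error")

  path <- tempfile(fileext = ".csv")
  write_spectra(sm, path)
  back <- read_spectra(path)
  expect_equal(back$X, sm$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, sm$labels)
  expect_equal(back$wavelengths, sm$wavelengths, tolerance = 1e-12)
})

test_that("ENVI write/read round-trips cubes in all interleaves", {
  set.seed(3)
  cube <- raw_cube(array(runif(4 * 4 * 5, 0, 1000), c(4, 4, 5)),
                   c(980, 1100, 1200, 1400, 1600))
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile()
    write_cube(cube, path, interleave = il)
    back <- read_cube(path)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
  }

  # wavelength count mismatch is a validation error
  path <- tempfile()
  write_cube(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("^bands = 5", "bands = 6", hdr)
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(read_cube(path), class = "wavesel_validation_error")
  expect_error(read_cube(tempfile()), class = "wavesel_format_error")
})

test_that("a 200-band fixture cube survives the ENVI round trip", {
  spec <- fixture_spec(q = 2, n_per_class = c(2, 1, 1), n_channels = 200,
                       informative_channels = c(50, 150),
                       effect_size = 0.1, seed = 9)
  gen <- make_synthetic_cube(spec, grid = c(1, 2), kernel_radius = 4,
                             cell_size = 16)
  path <- tempfile()
  write_cube(gen$raw, path, interleave = "bil")
  back <- read_cube(path)
  expect_identical(dim(back$data)[3], 200L)
  expect_equal(back$data, gen$raw$data)
})

test_that("full pipeline extracts normalized per-kernel spectra from a cube", {
  spec <- standard_fixtures()$cube_small
  gen <- make_synthetic_cube(spec, grid = c(2, 3))
  refl <- calibrate(gen$raw, gen$refs)
  out <- extract_spectra(refl, band = 20, min_area = 10, side = 16,
                         window = 3)
  expect_identical(nrow(out$sm$X), 6L)
  expect_true(all(abs(rowMeans(out$sm$X) - 1) < 1e-9))

  # masked variant averages only kernel pixels: exactly the planted
  # spectrum after the same smooth+normalize chain
  out_m <- extract_spectra(refl, band = 20, min_area = 10, side = 16,
                           window = 3, use_mask = TRUE)
  planted <- gen$truth$reflectance[1, ]
  chain <- normalize_spectrum(smooth_spectrum(
    as_spectrum(planted, refl$wavelengths), 3))$values
  expect_equal(out_m$sm$X[1, ], chain, tolerance = 1e-9,
               ignore_attr = TRUE)
})
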