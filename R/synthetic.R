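# Synthetic NIR spectra and plate-cube generators with planted ground truth.
# The spectra emulate the statistical structure of kernel-level NIR
# reflectance: a smooth shared baseline (broad Gaussians -> strong
# inter-channel correlation), small class-specific bumps confined to a known
# set of informative channels, multiplicative (lognormal) scatter between
# samples and additive per-channel Gaussian noise.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic spectra fixture
#'
#' @param q number of classes (>= 2).
#' @param n_per_class named integer vector `c(cal=, val=, pre=)`: samples
#'   per class in each split.
#' @param n_channels number of spectral channels Ch.
#' @param informative_channels 1-based indices of the channels carrying
#'   class signal.
#' @param effect_size amplitude scale of the class-specific bumps,
#'   in reflectance units relative to a baseline of order 1.
#' @param bump_width Gaussian bump standard deviation in channels; bumps
#'   are truncated at 3 widths, so class signal is strictly local.
#' @param scatter_sd standard deviation of the lognormal multiplicative
#'   scatter applied per sample.
#' @param noise_sd standard deviation of additive per-channel noise.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   spec (seed included).
#' @param preprocess default preprocessing applied by
#'   [make_synthetic_spectra()]: `"full"` (mean filter + average
#'   normalization, the standard chain), `"normalize"` (normalization
#'   only: keeps class signal channel-exact for recovery benchmarks) or
#'   `"none"`.
#' @param wl_range wavelength range in nm mapped linearly onto the channels.
#' @return a `"fixture_spec"` list.
#' @export
fixture_spec <- function(q, n_per_class, n_channels, informative_channels,
                         effect_size, bump_width = 1.5, scatter_sd = 0.05,
                         noise_sd = 0.01, seed = 1L,
                         preprocess = c("full", "normalize", "none"),
                         wl_range = c(975, 1645)) {
  preprocess <- match.arg(preprocess)
  q <- as.integer(q)
  if (q < 2L) abort_validation("q must be >= 2")
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L) n_per_class <- rep(n_per_class, length.out = 3L)
  names(n_per_class) <- c("cal", "val", "pre")
  informative_channels <- sort(unique(as.integer(informative_channels)))
  if (any(informative_channels < 1L) || any(informative_channels > n_channels))
    abort_validation("informative_channels outside 1..", n_channels)
  if (effect_size < 0 || scatter_sd < 0 || noise_sd < 0)
    abort_validation("effect_size and noise/scatter sds must be >= 0")
  structure(list(q = q, n_per_class = n_per_class,
                 n_channels = as.integer(n_channels),
                 informative_channels = informative_channels,
                 effect_size = effect_size, bump_width = bump_width,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed), preprocess = preprocess,
                 wl_range = as.numeric(wl_range)),
            class = "fixture_spec")
}

# Deterministic shared baseline and per-class bump amplitudes for a spec.
# Consumes the RNG stream (callers wrap in with_seed).
fixture_signal <- function(spec) {
  ch <- seq_len(spec$n_channels)
  n_humps <- 4L
  a <- stats::runif(n_humps, 0.10, 0.40)
  ctr <- stats::runif(n_humps, 1, spec$n_channels)
  wd <- stats::runif(n_humps, spec$n_channels / 8, spec$n_channels / 4)
  baseline <- rep(1, spec$n_channels)
  for (m in seq_len(n_humps))
    baseline <- baseline + a[m] * exp(-((ch - ctr[m])^2) / (2 * wd[m]^2))
  ni <- length(spec$informative_channels)
  # each informative channel assigns every class a +/- effect sign. Using
  # distinct non-constant sign patterns keeps the per-channel spread equal,
  # the channels mutually non-redundant, and the class means at hypercube
  # vertices (never collinear, so linear one-hot regression is not masked)
  if (spec$q <= 10L) {
    pats <- unname(as.matrix(expand.grid(rep(list(c(-1, 1)), spec$q))))
    pats <- pats[rowSums(pats) != spec$q & rowSums(pats) != -spec$q, ,
                 drop = FALSE]
    take <- if (ni <= nrow(pats)) sample(nrow(pats), ni)
            else sample(nrow(pats), ni, replace = TRUE)
    amp <- t(pats[take, , drop = FALSE]) * spec$effect_size
  } else {
    amp <- matrix(sample(c(-1, 1), spec$q * ni, TRUE), spec$q, ni)
    for (j in seq_len(ni))  # forbid constant columns
      if (abs(sum(amp[, j])) == spec$q) amp[1L, j] <- -amp[1L, j]
    amp <- amp * spec$effect_size
  }
  # truncated Gaussian bump profiles, one column per informative channel
  half <- ceiling(3 * spec$bump_width)
  profiles <- matrix(0, spec$n_channels, ni)
  for (j in seq_len(ni)) {
    c0 <- spec$informative_channels[j]
    sup <- max(1L, c0 - half):min(spec$n_channels, c0 + half)
    profiles[sup, j] <- exp(-((sup - c0)^2) / (2 * spec$bump_width^2))
  }
  list(baseline = baseline, amp = amp, profiles = profiles)
}

#' Generate synthetic spectra with planted informative channels
#'
#' Each sample is `(baseline + sum of its class's bumps) * exp(N(0,
#' scatter_sd)) + N(0, noise_sd)` per channel, optionally followed by the
#' standard preprocessing chain (mean filter window 5, then average
#' normalization). Class differences are confined to the informative
#' channels' bump support before noise.
#'
#' @param spec a [fixture_spec()].
#' @param preprocess `"full"`, `"normalize"` or `"none"`; defaults to the
#'   spec's own `preprocess` field.
#' @param permute_labels permute class labels after generation (a null
#'   control: destroys any label-channel association while preserving the
#'   marginal spectra distribution).
#' @return list with `sm` (a `"spectra_matrix"` with cal/val/pre splits)
#'   and `truth` (informative channels, per-class bump amplitudes, seed).
#' @export
make_synthetic_spectra <- function(spec, preprocess = NULL,
                                   permute_labels = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  preprocess <- match.arg(preprocess %||% spec$preprocess,
                          c("full", "normalize", "none"))
  with_seed(spec$seed, {
    sig <- fixture_signal(spec)
    n_tot_class <- sum(spec$n_per_class)
    n <- n_tot_class * spec$q
    labels <- rep(0:(spec$q - 1L), each = n_tot_class)
    splits <- rep(rep(c("cal", "val", "pre"), times = spec$n_per_class),
                  times = spec$q)
    class_mean <- matrix(rep(sig$baseline, spec$q), spec$q,
                         spec$n_channels, byrow = TRUE) +
      sig$amp %*% t(sig$profiles)
    X <- class_mean[labels + 1L, , drop = FALSE]
    scatter <- exp(stats::rnorm(n, 0, spec$scatter_sd))
    X <- X * scatter
    X <- X + matrix(stats::rnorm(n * spec$n_channels, 0, spec$noise_sd),
                    n, spec$n_channels)
    if (permute_labels) labels <- sample(labels)
    wl <- seq(spec$wl_range[1L], spec$wl_range[2L],
              length.out = spec$n_channels)
    if (preprocess != "none") {
      w <- min(5L, spec$n_channels - (1L - spec$n_channels %% 2L))
      if (w %% 2L == 0L) w <- w - 1L
      for (i in seq_len(n)) {
        s <- as_spectrum(X[i, ], wl)
        if (preprocess == "full") s <- smooth_spectrum(s, w)
        X[i, ] <- normalize_spectrum(s)$values
      }
    }
    list(sm = spectra_matrix(X, labels, wl, splits),
         truth = list(informative_channels = spec$informative_channels,
                      amplitudes = sig$amp, baseline = sig$baseline,
                      seed = spec$seed))
  })
}

#' Generate a synthetic hyperspectral plate cube
#'
#' Builds a raw cube plus white/dark reference frames for a gridded plate
#' of disk-shaped kernels on a low-reflectance background, such that
#' [calibrate()] recovers the planted reflectance exactly (the raw cube is
#' constructed by inverting the calibration identity). Every pixel of a
#' kernel carries that kernel's spectrum.
#'
#' @param spec a [fixture_spec()]; kernels get class labels round-robin.
#' @param grid integer vector `c(nrow, ncol)` of the kernel layout.
#' @param kernel_radius disk radius in pixels.
#' @param cell_size pixel pitch between kernel centers (must exceed the
#'   kernel diameter).
#' @param background_level flat background reflectance.
#' @return list with `raw` (a `"raw_cube"`), `refs`
#'   (`"reference_frames"`), and `truth` (kernel centers, labels, planted
#'   per-kernel spectra, informative channels).
#' @export
make_synthetic_cube <- function(spec, grid = c(5L, 5L), kernel_radius = 6L,
                                cell_size = 32L, background_level = 0.03) {
  stopifnot(inherits(spec, "fixture_spec"))
  grid <- as.integer(grid); kernel_radius <- as.integer(kernel_radius)
  cell_size <- as.integer(cell_size)
  if (2L * kernel_radius + 2L >= cell_size)
    abort_validation("kernels would overlap: need cell_size > 2*radius + 2")
  nk <- prod(grid)
  with_seed(spec$seed, {
    sig <- fixture_signal(spec)
    labels <- rep(0:(spec$q - 1L), length.out = nk)
    clean <- matrix(rep(sig$baseline, nk), nk, spec$n_channels,
                    byrow = TRUE) +
      sig$amp[labels + 1L, , drop = FALSE] %*% t(sig$profiles)
    if (spec$scatter_sd > 0)
      clean <- clean * exp(stats::rnorm(nk, 0, spec$scatter_sd))
    refl <- 0.55 * clean / max(clean)  # keep reflectance comfortably < 1
    nr <- grid[1L] * cell_size; ncl <- grid[2L] * cell_size
    cube <- array(background_level, c(nr, ncl, spec$n_channels))
    centers <- matrix(0, nk, 2L)
    k <- 0L
    for (gi in seq_len(grid[1L])) for (gj in seq_len(grid[2L])) {
      k <- k + 1L
      cr <- (gi - 1L) * cell_size + cell_size %/% 2L
      cc <- (gj - 1L) * cell_size + cell_size %/% 2L
      centers[k, ] <- c(cr, cc)
      rr <- (cr - kernel_radius):(cr + kernel_radius)
      cc2 <- (cc - kernel_radius):(cc + kernel_radius)
      dmat <- outer((rr - cr)^2, (cc2 - cc)^2, "+")
      inside <- dmat <= kernel_radius^2
      for (b in seq_len(spec$n_channels)) {
        sl <- cube[rr, cc2, b]
        sl[inside] <- refl[k, b]
        cube[rr, cc2, b] <- sl
      }
    }
    wl <- seq(spec$wl_range[1L], spec$wl_range[2L],
              length.out = spec$n_channels)
    white <- rep(1000, spec$n_channels)
    dark <- rep(100, spec$n_channels)
    wh <- broadcast_ref(white, dim(cube), "white")
    dk <- broadcast_ref(dark, dim(cube), "dark")
    raw <- dk + cube * (wh - dk)
    list(raw = raw_cube(raw, wl),
         refs = reference_frames(white, dark),
         truth = list(centers = centers, labels = labels,
                      reflectance = refl, kernel_radius = kernel_radius,
                      informative_channels = spec$informative_channels,
                      background_level = background_level))
  })
}

#' Named fixture presets
#'
#' Pinned-seed presets used throughout the test-bench:
#' \describe{
#'   \item{easy}{q = 3, 50 channels, 4 informative, large effect: linearly
#'     separable.}
#'   \item{standard}{q = 4, 100 channels, 8 informative, 200/100/100 per
#'     class: the channel-recovery benchmark.}
#'   \item{hard}{q = 8, 100 channels, 10 informative, small effect and more
#'     noise: overlapping classes, not linearly separable.}
#'   \item{cube_small}{a 5 x 5 plate-cube companion spec (50 bands).}
#' }
#' @return named list of `"fixture_spec"` objects.
#' @export
standard_fixtures <- function() {
  list(
    easy = fixture_spec(q = 3, n_per_class = c(60, 30, 30), n_channels = 50,
                        informative_channels = c(8, 18, 28, 40),
                        effect_size = 0.35, bump_width = 1.5,
                        scatter_sd = 0.05, noise_sd = 0.003, seed = 101L),
    standard = fixture_spec(q = 4, n_per_class = c(200, 100, 100),
                            n_channels = 100,
                            informative_channels = c(10, 23, 36, 47, 59,
                                                     71, 84, 96),
                            effect_size = 0.12, bump_width = 0.5,
                            scatter_sd = 0.05, noise_sd = 0.12,
                            seed = 202L, preprocess = "normalize"),
    hard = fixture_spec(q = 8, n_per_class = c(200, 100, 100),
                        n_channels = 100,
                        informative_channels = c(9, 20, 31, 42, 53, 64,
                                                 75, 86, 92, 98),
                        effect_size = 0.035, bump_width = 2,
                        scatter_sd = 0.08, noise_sd = 0.08, seed = 303L),
    cube_small = fixture_spec(q = 5, n_per_class = c(10, 5, 10),
                              n_channels = 50,
                              informative_channels = c(10, 25, 40),
                              effect_size = 0.2, bump_width = 1.5,
                              scatter_sd = 0.04, noise_sd = 0, seed = 404L)
  )
}
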