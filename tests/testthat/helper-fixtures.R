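# Shared fixtures and small oracles. Expensive objects are computed once
# per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

std_gen <- function() cached("std_gen", {
  make_synthetic_spectra(standard_fixtures()$standard)
})

easy_gen <- function() cached("easy_gen", {
  make_synthetic_spectra(standard_fixtures()$easy)
})

hard_gen <- function() cached("hard_gen", {
  make_synthetic_spectra(standard_fixtures()$hard)
})

# CNN-FS score vectors on the standard fixture, one per seed; shared
# between the recovery and selector-ordering tests. 150 epochs at the
# initial learning rate (the desk-scale benchmark protocol).
std_cnn_fs <- function(seed, epochs = 150L) {
  cached(paste0("std_cnn_fs_", seed, "_", epochs), {
    cnn_fs_scores(std_gen()$sm,
                  cfg = train_config(epochs = epochs, lr_period = epochs,
                                     batch_size = 128L,
                                     lambda_penalty = 0.1, seed = seed),
                  checkpoint = "final")
  })
}

# independent linear oracle: one-hot least squares + argmax (base lm)
ols_argmax_accuracy <- function(sm_train, sm_test = sm_train) {
  q <- max(sm_train$labels) + 1L
  Y <- sapply(0:(q - 1L), function(k) as.numeric(sm_train$labels == k))
  fit <- stats::lm.fit(cbind(1, sm_train$X), Y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0  # collinear columns carry no extra information
  pred <- cbind(1, sm_test$X) %*% cf
  mean((max.col(pred) - 1L) == sm_test$labels)
}

# brute-force per-pixel mean spectrum (loop oracle)
brute_mean_spectrum <- function(kc, mask = NULL) {
  d <- dim(kc$data)
  out <- numeric(d[3L])
  n <- 0L
  for (b in seq_len(d[3L])) {
    acc <- 0
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
      if (is.null(mask) || mask[i, j]) {
        acc <- acc + kc$data[i, j, b]
        if (b == 1L) n <- n + 1L
      }
    }
    out[b] <- acc
  }
  out / n
}

# reflectance cube with planted bright disks on a dark background
disk_cube <- function(centers, radius = 5, nrow_px = 60, ncol_px = 60,
                      bands = 6, fg = 0.8, bg = 0.05) {
  arr <- array(bg, c(nrow_px, ncol_px, bands))
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(nrow_px)) for (j in seq_len(ncol_px)) {
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2)
        arr[i, j, ] <- fg
    }
  }
  reflectance_cube(arr, seq(1000, 1000 + bands - 1))
}
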