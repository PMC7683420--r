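# Benchmark orchestration: the full cube -> spectra pipeline, the
# selector x classifier comparison matrix, and data-first exports of the
# score / consensus / surface artifacts.

#' Full preprocessing: reflectance cube to per-kernel spectra
#'
#' Segments kernels, extracts a square window per kernel, averages to a
#' mean spectrum, then smooths (mean filter) and average-normalizes.
#'
#' @param cube a `"reflectance_cube"`.
#' @param band segmentation band (1-based).
#' @param min_area minimum component area in pixels.
#' @param side ROI side length in pixels.
#' @param window smoothing window.
#' @param use_mask average only the segmented foreground pixels inside the
#'   window instead of the full square.
#' @param labels optional integer labels, one per detected kernel (in
#'   region order); defaults to 0.
#' @return list with `sm` (a `"spectra_matrix"`) and `regions`.
#' @export
extract_spectra <- function(cube, band = 20L, min_area = 10L, side = 30L,
                            window = 5L, use_mask = FALSE, labels = NULL) {
  regions <- segment_kernels(cube, band = band, min_area = min_area)
  if (!length(regions))
    abort_validation("no kernel regions found in the cube")
  specs <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    kc <- extract_kernel_cube(cube, regions[[i]], side = side)
    mask <- NULL
    if (use_mask) {
      rows <- kc$origin["row"]:(kc$origin["row"] + side - 1L)
      cols <- kc$origin["col"]:(kc$origin["col"] + side - 1L)
      mask <- regions[[i]]$pixel_mask[rows, cols]
      if (!any(mask)) mask <- NULL
    }
    s <- kernel_mean_spectrum(kc, mask = mask)
    specs[[i]] <- normalize_spectrum(smooth_spectrum(s, window = window))
  }
  labels <- labels %||% rep(0L, length(regions))
  if (length(labels) != length(regions))
    abort_validation("labels length (", length(labels),
                     ") != number of regions (", length(regions), ")")
  list(sm = build_spectra_matrix(specs, labels), regions = regions)
}

selector_scores <- function(sm, method, seed = 1L, fs_cfg = NULL,
                            svm_C = 20) {
  switch(method,
    cnn_fs = cnn_fs_scores(sm, cfg = fs_cfg %||% train_config(seed = seed)),
    ufs_chi2 = ufs_chi2_scores(sm),
    etc = etc_scores(sm, seed = seed),
    svm_fs = svm_fs_scores(sm, C = svm_C),
    abort_validation("unknown selector '", method, "'"))
}

#' Run the selector-by-classifier comparison
#'
#' For every selector (including `"none"` = full spectra) and classifier,
#' selects top-k channels on the calibration split, tunes the classifier's
#' hyperparameters on the validation split, and reports accuracy on all
#' three splits. Cell failures are recorded and the run continues.
#'
#' @param sm a `"spectra_matrix"` with cal/val/pre splits.
#' @param selectors subset of `c("none", "cnn_fs", "ufs_chi2", "etc",
#'   "svm_fs")`.
#' @param classifiers subset of `c("cnn_att", "plsda", "rbf_svc")`.
#' @param k channels kept per selector.
#' @param seed master seed; all per-cell seeds derive from it.
#' @param cnn_cfg [train_config()] for the CNN classifier (and, unless
#'   `fs_cfg` is given, the CNN selector).
#' @param fs_cfg optional separate config for [cnn_fs_scores()].
#' @param nn_full,nn_selected attention widths for full-spectra vs
#'   selected-channel models.
#' @param C_grid,gamma_grid RBF-SVC search grids.
#' @param comp_range PLSDA component candidates (default 1..min(Ch, N-1)).
#' @param svm_C penalty for the sparse-SVM selector.
#' @return a `"comparison_report"` data.frame with columns selector,
#'   classifier, n_channels, parameters, calibration, validation,
#'   prediction; failures (if any) in `attr(, "errors")`.
#' @export
run_comparison <- function(sm,
                           selectors = c("none", "cnn_fs", "ufs_chi2",
                                         "etc", "svm_fs"),
                           classifiers = c("cnn_att", "plsda", "rbf_svc"),
                           k = 60L, seed = 1L,
                           cnn_cfg = train_config(seed = seed),
                           fs_cfg = NULL,
                           nn_full = 64L, nn_selected = 32L,
                           C_grid = 10^(1:12), gamma_grid = 10^(-9:2),
                           comp_range = NULL, svm_C = 20) {
  stopifnot(inherits(sm, "spectra_matrix"))
  if (is.null(sm$splits)) abort_validation("sm needs cal/val/pre splits")
  selectors <- match.arg(selectors, several.ok = TRUE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  ch_all <- ncol(sm$X)
  if (k > ch_all) abort_validation("k (", k, ") exceeds Ch (", ch_all, ")")
  rows <- list(); errors <- list()
  for (sel in selectors) {
    sub <- sm; sel_k <- ch_all
    if (sel != "none") {
      sc <- tryCatch(
        selector_scores(sm, sel, seed = seed, fs_cfg = fs_cfg %||%
                          cnn_cfg, svm_C = svm_C),
        error = function(e) e)
      if (inherits(sc, "error")) {
        errors[[paste0(sel, "/*")]] <- conditionMessage(sc)
        next
      }
      keep <- sort(select_top_k(sc, k)$selected)
      sub <- sm_subset(sm, channels = keep)
      sel_k <- k
    }
    splits <- list(cal = sm_subset(sub, split = "cal"),
                   val = sm_subset(sub, split = "val"),
                   pre = sm_subset(sub, split = "pre"))
    for (clf in classifiers) {
      cell <- tryCatch(
        fit_cell(clf, splits, sel_k == ch_all, cnn_cfg, nn_full,
                 nn_selected, C_grid, gamma_grid, comp_range),
        error = function(e) e)
      if (inherits(cell, "error")) {
        errors[[paste(sel, clf, sep = "/")]] <- conditionMessage(cell)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        selector = sel, classifier = clf, n_channels = sel_k,
        parameters = cell$parameters,
        calibration = cell$acc["cal"], validation = cell$acc["val"],
        prediction = cell$acc["pre"], row.names = NULL)
    }
  }
  report <- do.call(rbind, rows) %||%
    data.frame(selector = character(), classifier = character())
  rownames(report) <- NULL
  class(report) <- c("comparison_report", "data.frame")
  attr(report, "errors") <- errors
  if (length(errors))
    warning(length(errors), " comparison cell(s) failed; see attr(report,",
            " 'errors')", call. = FALSE)
  report
}

fit_cell <- function(clf, splits, full_spectra, cnn_cfg, nn_full,
                     nn_selected, C_grid, gamma_grid, comp_range) {
  acc3 <- function(predict_fun) {
    vapply(splits, function(s)
      mean(predict_fun(s$X) == s$labels), 0)
  }
  if (clf == "plsda") {
    sr <- plsda_select_comp(splits, comp_range = comp_range)
    list(parameters = paste0("comp = ", sr$best_comp),
         acc = acc3(function(X)
           plsda_predict(sr$model, X, comp = sr$best_comp)))
  } else if (clf == "rbf_svc") {
    gs <- rbf_svc_grid_search(splits, C_grid = C_grid,
                              gamma_grid = gamma_grid)
    list(parameters = sprintf("C = %.0e, g = %.0e", gs$best$C,
                              gs$best$gamma),
         acc = acc3(function(X) rbf_svc_predict(gs$model, X)))
  } else if (clf == "cnn_att") {
    nn <- if (full_spectra) nn_full else nn_selected
    fit <- cnn_att_fit(splits, nn_units = nn, cfg = cnn_cfg)
    list(parameters = paste0("nn = ", nn),
         acc = acc3(function(X) cnn_att_predict(fit, X)$labels))
  } else abort_validation("unknown classifier '", clf, "'")
}

#' Export score / selection / consensus plot data
#'
#' Writes the comparison artifacts as data-first CSVs: per-selector score
#' curves (`scores.csv`), selected-band masks with the conventional
#' stacked display offsets 0.2, 0.4, ... (`selected_bands.csv`), and
#' per-channel consensus levels (`consensus.csv`). Rendering is optional
#' (`render = TRUE` additionally writes PNGs) so headless runs never need
#' a display.
#'
#' @param scores named list of `"importance_scores"`.
#' @param selections named list of `"selection_result"` over the same
#'   channels.
#' @param out_dir output directory (created if missing).
#' @param wavelengths channel wavelength axis.
#' @param render also write PNG figures.
#' @return invisible vector of written paths.
#' @export
export_score_plot_data <- function(scores, selections, out_dir,
                                   wavelengths = NULL, render = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- length(scores[[1L]]$scores)
  wl <- wavelengths %||% scores[[1L]]$wavelengths %||% seq_len(ch)
  sc <- do.call(rbind, lapply(names(scores), function(nm)
    data.frame(method = nm, channel_index = seq_len(ch),
               wavelength_nm = wl, score = scores[[nm]]$scores)))
  p1 <- file.path(out_dir, "scores.csv")
  utils::write.csv(sc, p1, row.names = FALSE)
  offs <- 0.2 * seq_along(selections)
  mk <- do.call(rbind, lapply(seq_along(selections), function(i) {
    selected <- as.integer(seq_len(ch) %in% selections[[i]]$selected)
    data.frame(method = names(selections)[i],
               channel_index = seq_len(ch), wavelength_nm = wl,
               selected = selected, display_offset = offs[i])
  }))
  p2 <- file.path(out_dir, "selected_bands.csv")
  utils::write.csv(mk, p2, row.names = FALSE)
  cons <- selector_consensus(selections, ch)
  p3 <- file.path(out_dir, "consensus.csv")
  utils::write.csv(data.frame(channel_index = seq_len(ch),
                              wavelength_nm = wl, level = cons),
                   p3, row.names = FALSE)
  paths <- c(p1, p2, p3)
  if (render) {
    p4 <- file.path(out_dir, "scores.png")
    grDevices::png(p4, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::matplot(wl, vapply(scores, `[[`, numeric(ch), "scores"),
                      type = "l", lty = 1, xlab = "wavelength (nm)",
                      ylab = "score")
    graphics::legend("topright", legend = names(scores), lty = 1,
                     col = seq_along(scores))
    paths <- c(paths, p4)
  }
  invisible(paths)
}

#' Write a comparison report and grid surface to disk
#'
#' @param report a `"comparison_report"`.
#' @param path CSV output path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
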