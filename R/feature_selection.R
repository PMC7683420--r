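#' Per-channel importance scores
#'
#' Container for the score vector any selector produces, with provenance.
#'
#' @param scores finite numeric vector, one score per channel.
#' @param method one of `"cnn_fs"`, `"ufs_chi2"`, `"etc"`, `"svm_fs"`.
#' @param wavelengths optional wavelength axis (nm).
#' @param metadata list of selector settings (config, seed, ...).
#' @export
importance_scores <- function(scores, method, wavelengths = NULL,
                              metadata = list()) {
  scores <- as.numeric(scores)
  check_finite(scores, "importance scores")
  method <- match.arg(method, c("cnn_fs", "ufs_chi2", "etc", "svm_fs"))
  structure(list(scores = scores, method = method,
                 wavelengths = wavelengths, metadata = metadata),
            class = "importance_scores")
}

#' @export
print.importance_scores <- function(x, ...) {
  cat("<importance_scores> ", x$method, ", ", length(x$scores),
      " channels, top channel ", which.max(x$scores), "\n", sep = "")
  invisible(x)
}

#' Embedded CNN feature-selector scores (CNN-FS)
#'
#' Trains the selection-layer CNN with the sparsity-penalized loss
#' ([fs_loss()]) and returns `relu(W_SL)` as the channel importance
#' scores: the model is pushed to classify well while driving the scores
#' of channels that do not help toward zero. Scores are read at the epoch
#' of best validation accuracy by default.
#'
#' @param data a split `"spectra_matrix"` (cal/val) or `list(cal=, val=)`.
#' @param cfg a [train_config()]; `lambda_penalty > 0` is required for
#'   meaningful sparsity.
#' @param checkpoint `"best"` (validation-best epoch) or `"final"`.
#' @return an `"importance_scores"` object (method `"cnn_fs"`); the
#'   trained model is attached as `metadata$fit`.
#' @export
cnn_fs_scores <- function(data, cfg = train_config(),
                          checkpoint = c("best", "final")) {
  checkpoint <- match.arg(checkpoint)
  if (cfg$lambda_penalty <= 0)
    warning("lambda_penalty <= 0: the selection layer is not pushed ",
            "toward sparsity", call. = FALSE)
  fit <- train_cnn(data, head = "sl", cfg = cfg)
  w <- sl_weights(fit, checkpoint = checkpoint)
  d <- split_cal_val(data)
  importance_scores(relu(w), "cnn_fs", d$cal$wavelengths,
                    metadata = list(cfg = cfg, checkpoint = checkpoint,
                                    fit = fit))
}

#' Multi-restart (ensemble) CNN feature-selector scores
#'
#' Embedded selection scores vary between training restarts: the sparsity
#' penalty keeps a sufficient channel subset per run, and which redundant
#' channel survives depends on the seed. Averaging the score vectors of
#' several restarts is the recommended way to obtain a stable final
#' ranking; channels consistently defended across restarts dominate.
#'
#' @inheritParams cnn_fs_scores
#' @param seeds integer vector of training seeds, one run each (cfg's own
#'   seed is ignored).
#' @return an `"importance_scores"` object whose scores are the mean of
#'   the per-seed `relu(W_SL)` vectors; per-seed vectors are kept in
#'   `metadata$per_seed`.
#' @export
cnn_fs_ensemble_scores <- function(data, seeds, cfg = train_config(),
                                   checkpoint = c("best", "final")) {
  checkpoint <- match.arg(checkpoint)
  if (!length(seeds)) abort_validation("need at least one seed")
  per <- lapply(as.integer(seeds), function(sd) {
    cfg$seed <- sd
    cnn_fs_scores(data, cfg = cfg, checkpoint = checkpoint)$scores
  })
  d <- split_cal_val(data)
  importance_scores(Reduce(`+`, per) / length(per), "cnn_fs",
                    d$cal$wavelengths,
                    metadata = list(cfg = cfg, seeds = as.integer(seeds),
                                    checkpoint = checkpoint,
                                    per_seed = per))
}

#' Chi-square univariate feature scores
#'
#' The standard nonnegative-feature univariate score for classification:
#' for each channel, the chi-square statistic of the observed per-class
#' feature sums against expectations proportional to class frequencies.
#' A channel identical across classes scores 0; features must be
#' nonnegative (normalized reflectance is), or set `shift = TRUE` to
#' subtract the per-channel minimum first.
#'
#' @param data a `"spectra_matrix"` (the cal split is used when splits are
#'   present).
#' @param shift shift each channel by its minimum to enforce
#'   nonnegativity.
#' @export
ufs_chi2_scores <- function(data, shift = FALSE) {
  sm <- if (inherits(data, "spectra_matrix") && !is.null(data$splits))
    sm_subset(data, split = "cal") else data
  stopifnot(inherits(sm, "spectra_matrix"))
  X <- sm$X
  if (shift) X <- sweep(X, 2L, apply(X, 2L, min), "-")
  if (any(X < 0))
    abort_validation("chi-square scores need nonnegative features; ",
                     "use shift = TRUE")
  y <- factor(sm$labels)
  # observed: per-class column sums; expected: total column sum x class freq
  obs <- rowsum(X, y)                    # q x Ch
  freq <- as.numeric(table(y)) / nrow(X)
  tot <- colSums(X)
  expd <- outer(freq, tot)               # q x Ch
  stat <- colSums((obs - expd)^2 / ifelse(expd == 0, 1, expd))
  stat[tot == 0] <- 0
  importance_scores(stat, "ufs_chi2", sm$wavelengths)
}

#' Extremely-randomized-trees importance scores
#'
#' Mean impurity-decrease importances from an extra-trees ensemble
#' (ranger with `splitrule = "extratrees"`), normalized to sum to 1.
#'
#' @param data a `"spectra_matrix"` (cal split if splits present).
#' @param n_trees ensemble size.
#' @param seed integer seed; identical seeds give identical scores.
#' @export
etc_scores <- function(data, n_trees = 100L, seed = 1L) {
  sm <- if (inherits(data, "spectra_matrix") && !is.null(data$splits))
    sm_subset(data, split = "cal") else data
  stopifnot(inherits(sm, "spectra_matrix"))
  if (n_trees < 1L) abort_validation("n_trees must be >= 1")
  if (length(unique(sm$labels)) < 2L)
    abort_validation("need at least two classes")
  df <- as.data.frame(sm$X)
  names(df) <- paste0("ch", seq_len(ncol(sm$X)))
  df$.y <- factor(sm$labels)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = as.integer(n_trees),
                        splitrule = "extratrees",
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
  imp <- pmax(fit$variable.importance, 0)
  s <- sum(imp)
  importance_scores(if (s > 0) imp / s else imp, "etc", sm$wavelengths,
                    metadata = list(n_trees = n_trees, seed = seed))
}

# L1-penalized squared-hinge linear SVM, one class vs rest, fitted by
# accelerated proximal gradient (FISTA with restart) on centered features.
# Objective: C/n * sum_i max(0, 1 - s_i (x_i'w + b))^2 + ||w||_1
# The squared hinge is smooth, so its gradient step pairs with the L1
# soft-threshold prox; centering only shifts the intercept, not w.
l1_svm_binary <- function(X, s, C, max_iter = 5000L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  obj <- function(w, b) {
    m <- pmax(0, 1 - s * (drop(Xc %*% w) + b))
    (C / n) * sum(m * m)
  }
  # Lipschitz bound of the smooth part: 2C/n * ||[Xc 1]||_2^2
  L <- 2 * C / n * (sum(Xc * Xc) + n)
  w <- rep(0, p); b <- 0
  yw <- w; yb <- b
  t_acc <- 1
  f_prev <- obj(w, b) # = C at the zero solution
  for (it in seq_len(max_iter)) {
    m <- pmax(0, 1 - s * (drop(Xc %*% yw) + yb))
    gw <- -(2 * C / n) * drop(crossprod(Xc, s * m))
    gb <- -(2 * C / n) * sum(s * m)
    w_new <- yw - gw / L
    w_new <- sign(w_new) * pmax(abs(w_new) - 1 / L, 0)
    b_new <- yb - gb / L
    # restart the momentum when the objective increases
    f_new <- obj(w_new, b_new) + sum(abs(w_new))
    if (f_new > f_prev + 1e-12) {
      yw <- w; yb <- b; t_acc <- 1
      next
    }
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    yw <- w_new + (t_acc - 1) / t_next * (w_new - w)
    yb <- b_new + (t_acc - 1) / t_next * (b_new - b)
    conv <- abs(f_prev - f_new) < tol * (1 + abs(f_new))
    w <- w_new; b <- b_new; t_acc <- t_next; f_prev <- f_new
    if (conv && it > 1L)
      return(list(w = w, b = b - sum(w * mu), iters = it,
                  converged = TRUE))
  }
  list(w = w, b = b - sum(w * mu), iters = max_iter, converged = FALSE)
}

#' Sparse linear SVM importance scores
#'
#' Fits an L1-penalized (squared-hinge) linear SVM one-vs-rest per class;
#' the importance of a channel is the sum over classes of the absolute
#' fitted coefficients. The L1 term fixes the coefficients of
#' uninformative channels at exactly zero, so their score is 0.
#'
#' @param data a `"spectra_matrix"` (cal split if splits present).
#' @param C penalty coefficient of the hinge term (larger C = weaker
#'   sparsity; the default keeps informative normalized-reflectance
#'   channels while zeroing noise).
#' @param max_iter,tol solver controls.
#' @export
svm_fs_scores <- function(data, C = 20, max_iter = 5000L, tol = 1e-8) {
  sm <- if (inherits(data, "spectra_matrix") && !is.null(data$splits))
    sm_subset(data, split = "cal") else data
  stopifnot(inherits(sm, "spectra_matrix"))
  classes <- sort(unique(sm$labels))
  if (length(classes) < 2L) abort_validation("need at least two classes")
  scores <- rep(0, ncol(sm$X))
  its <- integer(0)
  for (cl in classes) {
    s <- ifelse(sm$labels == cl, 1, -1)
    fit <- l1_svm_binary(sm$X, s, C, max_iter = max_iter, tol = tol)
    if (!fit$converged)
      stop_wavesel("sparse linear SVM did not converge for class ", cl,
                   " within ", max_iter, " iterations (C = ", C,
                   "); increase max_iter or reduce C",
                   class = "wavesel_convergence_error")
    scores <- scores + abs(fit$w)
    its <- c(its, fit$iters)
  }
  importance_scores(scores, "svm_fs", sm$wavelengths,
                    metadata = list(C = C, iters = its))
}

#' Select the top-k channels by score
#'
#' Channels are ranked by descending score; ties are broken by ascending
#' channel index, so the selection is stable and
#' `select_top_k(s, k)` is always a subset of `select_top_k(s, k + 1)`.
#'
#' @param scores an `"importance_scores"` object (or numeric vector).
#' @param k number of channels to keep (default 60).
#' @return a `"selection_result"`: list with `selected` (1-based channel
#'   indices in rank order), `k`, `method` and `wavelengths_nm` of the
#'   selected channels (if known).
#' @export
select_top_k <- function(scores, k = 60L) {
  if (inherits(scores, "importance_scores")) {
    s <- scores$scores; method <- scores$method; wl <- scores$wavelengths
  } else {
    s <- as.numeric(scores); method <- NA_character_; wl <- NULL
  }
  k <- as.integer(k)
  if (k < 1L || k > length(s))
    abort_validation("k must lie in 1..", length(s), ", got ", k)
  ord <- order(-s, seq_along(s))
  sel <- ord[seq_len(k)]
  structure(list(selected = sel, k = k, method = method,
                 wavelengths_nm = if (!is.null(wl)) wl[sel]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", if (is.na(x$method)) "scores" else x$method,
      ": top ", x$k, " channels\n", sep = "")
  invisible(x)
}

#' Cross-selector consensus counts
#'
#' For each channel, the number of selectors whose top-k set contains it
#' (the "L0"/"L1"/... consensus levels used to compare selected-band
#' maps).
#'
#' @param results list of `"selection_result"` objects over the same
#'   channel axis.
#' @param n_channels total channel count.
#' @return integer vector of length `n_channels` with values in
#'   `0..length(results)`.
#' @export
selector_consensus <- function(results, n_channels) {
  n_channels <- as.integer(n_channels)
  counts <- integer(n_channels)
  for (r in results) {
    stopifnot(inherits(r, "selection_result"))
    if (any(r$selected > n_channels))
      abort_validation("selection indices exceed n_channels")
    counts[r$selected] <- counts[r$selected] + 1L
  }
  counts
}

#' Write importance scores / selections to disk
#'
#' Scores as CSV (channel_index, wavelength_nm, score, method); a
#' selection as JSON (method, k, indices, wavelengths).
#' @param scores an `"importance_scores"`.
#' @param path output file path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "importance_scores"))
  df <- data.frame(channel_index = seq_along(scores$scores),
                   wavelength_nm = scores$wavelengths %||%
                     rep(NA_real_, length(scores$scores)),
                   score = scores$scores, method = scores$method)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @param sel a `"selection_result"`.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(list(method = sel$method, k = sel$k,
                            indices = sel$selected,
                            wavelengths_nm = sel$wavelengths_nm),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
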