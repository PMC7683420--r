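# The three classifier families compared on kernel spectra: the
# attention-gated CNN, PLS discriminant analysis with a latent-variable
# search, and an RBF SVM with a log-decade grid search.

#' Fit a PLS discriminant analysis model
#'
#' PLS2 regression (SIMPLS algorithm) of centered spectra on centered
#' one-hot class indicators with `comp` latent variables; the predicted
#' class is the argmax of the continuous response. With `comp` equal to
#' the rank of the centered data the fit coincides with multivariate
#' least squares.
#'
#' @param data a `"spectra_matrix"` (cal split is used if splits present).
#' @param comp number of latent variables, `1 <= comp <= min(Ch, N-1)`;
#'   silently reduced (with a warning) if the data's rank is lower.
#' @return a `"plsda_model"` with nested coefficient paths: `coef_path(m,
#'   a)` gives the coefficient matrix using the first `a` components.
#' @export
plsda_fit <- function(data, comp) {
  sm <- if (inherits(data, "spectra_matrix") && !is.null(data$splits))
    sm_subset(data, split = "cal") else data
  stopifnot(inherits(sm, "spectra_matrix"))
  X <- sm$X
  q <- max(sm$labels) + 1L
  comp <- as.integer(comp)
  if (comp < 1L || comp > min(ncol(X), nrow(X) - 1L))
    abort_validation("comp must lie in 1..min(Ch, N-1) = ",
                     min(ncol(X), nrow(X) - 1L))
  Y <- t(one_hot(sm$labels, q))          # N x q
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  p <- ncol(X)
  R <- matrix(0, p, comp); Q <- matrix(0, q, comp)
  TT <- matrix(0, nrow(X), comp); V <- matrix(0, p, comp)
  S <- crossprod(Xc, Yc)
  a_used <- 0L
  for (a in seq_len(comp)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (sv$d[1L] < 1e-12) break
    r <- sv$u[, 1L]
    tt <- drop(Xc %*% r)
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-10) break
    tt <- tt / nt; r <- r / nt
    pp <- drop(crossprod(Xc, tt))
    qq <- drop(crossprod(Yc, tt))
    v <- pp
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pp)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- qq; TT[, a] <- tt; V[, a] <- v
    a_used <- a
  }
  if (a_used < comp) {
    warning("rank of the centered data supports only ", a_used,
            " components; comp reduced from ", comp, call. = FALSE)
    R <- R[, seq_len(a_used), drop = FALSE]
    Q <- Q[, seq_len(a_used), drop = FALSE]
  }
  structure(list(R = R, Q = Q, x_mean = xm, y_mean = ym,
                 comp = a_used, q = q),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", x$comp, " components, ", x$q, " classes\n", sep = "")
  invisible(x)
}

#' Predict classes with a PLSDA model
#'
#' @param model a `"plsda_model"`.
#' @param X N x Ch matrix.
#' @param comp optionally use only the first `comp` components of the
#'   fitted path (defaults to all).
#' @return integer labels (0-based).
#' @export
plsda_predict <- function(model, X, comp = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  comp <- as.integer(comp %||% model$comp)
  if (comp < 1L || comp > model$comp)
    abort_validation("comp must lie in 1..", model$comp)
  B <- model$R[, seq_len(comp), drop = FALSE] %*%
    t(model$Q[, seq_len(comp), drop = FALSE])
  scores <- sweep(as.matrix(X), 2L, model$x_mean) %*% B
  scores <- sweep(scores, 2L, model$y_mean, "+")
  max.col(scores, ties.method = "first") - 1L
}

#' Choose the PLSDA component count on the validation split
#'
#' Fits once at the largest component count (the SIMPLS path is nested)
#' and scores every `comp` in `comp_range` on the validation set. Ties go
#' to the smallest `comp`.
#'
#' @param data a split `"spectra_matrix"` or `list(cal=, val=)`.
#' @param comp_range integer candidates (default 1 up to min(Ch, N-1)).
#' @return list with `best_comp`, `best_accuracy`, `curve` (data.frame
#'   comp, val_accuracy) and the fitted `model`.
#' @export
plsda_select_comp <- function(data, comp_range = NULL) {
  d <- split_cal_val(data)
  cal <- d$cal; val <- d$val
  maxc <- min(ncol(cal$X), nrow(cal$X) - 1L)
  comp_range <- sort(unique(as.integer(comp_range %||% seq_len(maxc))))
  if (!length(comp_range) || any(comp_range < 1L) || any(comp_range > maxc))
    abort_validation("comp_range must lie in 1..", maxc)
  model <- suppressWarnings(plsda_fit(cal, max(comp_range)))
  comp_range <- comp_range[comp_range <= model$comp]
  acc <- vapply(comp_range, function(a)
    mean(plsda_predict(model, val$X, comp = a) == val$labels), 0)
  best <- comp_range[which.max(acc)]  # which.max: first max = smallest comp
  list(best_comp = best, best_accuracy = max(acc),
       curve = data.frame(comp = comp_range, val_accuracy = acc),
       model = model)
}

#' Grid search for an RBF-kernel SVM classifier
#'
#' Fits one RBF SVM per (C, gamma) pair on the calibration split and
#' scores it on the validation split, returning the full accuracy surface
#' and the best pair (ties: smallest C, then smallest gamma). The default
#' grids are one point per decade over C = 10^1..10^12 and
#' gamma = 10^-9..10^2.
#'
#' @param data a split `"spectra_matrix"` or `list(cal=, val=)`.
#' @param C_grid,gamma_grid numeric grids (positive).
#' @return list with `surface` (data.frame C, gamma, val_accuracy),
#'   `best` (C, gamma, val_accuracy), and `model` (the refitted best
#'   e1071::svm).
#' @export
rbf_svc_grid_search <- function(data, C_grid = 10^(1:12),
                                gamma_grid = 10^(-9:2)) {
  d <- split_cal_val(data)
  cal <- d$cal; val <- d$val
  if (length(unique(cal$labels)) < 2L)
    abort_validation("grid search needs at least two classes")
  if (!length(C_grid) || !length(gamma_grid) ||
      any(C_grid <= 0) || any(gamma_grid <= 0))
    abort_validation("C_grid and gamma_grid must be positive and nonempty")
  C_grid <- sort(C_grid); gamma_grid <- sort(gamma_grid)
  yf <- factor(cal$labels, levels = sort(unique(cal$labels)))
  surface <- expand.grid(gamma = gamma_grid, C = C_grid)[, c("C", "gamma")]
  surface$val_accuracy <- NA_real_
  for (i in seq_len(nrow(surface))) {
    fit <- e1071::svm(x = cal$X, y = yf, kernel = "radial",
                      cost = surface$C[i], gamma = surface$gamma[i],
                      scale = FALSE)
    pred <- as.integer(as.character(predict(fit, val$X)))
    surface$val_accuracy[i] <- mean(pred == val$labels)
  }
  # ties -> smallest C then smallest gamma: order rows accordingly
  ord <- order(surface$C, surface$gamma)
  best_row <- ord[which.max(surface$val_accuracy[ord])]
  best <- surface[best_row, ]
  model <- e1071::svm(x = cal$X, y = yf, kernel = "radial",
                      cost = best$C, gamma = best$gamma, scale = FALSE)
  list(surface = surface, best = best, model = model)
}

#' Predict with a fitted RBF SVM
#' @param model the `model` element of [rbf_svc_grid_search()].
#' @param X N x Ch matrix.
#' @return integer labels (0-based).
#' @export
rbf_svc_predict <- function(model, X) {
  as.integer(as.character(predict(model, as.matrix(X))))
}

#' Fit the attention-gated CNN classifier (CNN-ATT)
#'
#' Trains the attention-block CNN with plain cross-entropy under `cfg`.
#' The customary bottleneck widths are 64 units for full-length spectra
#' and 32 for 60-channel selections.
#'
#' @param data a split `"spectra_matrix"` or `list(cal=, val=)`.
#' @param nn_units attention bottleneck width.
#' @param cfg a [train_config()].
#' @return a `"trained_cnn"` (see [train_cnn()]).
#' @export
cnn_att_fit <- function(data, nn_units = 64L, cfg = train_config()) {
  train_cnn(data, head = "att", cfg = cfg, nn_units = nn_units)
}

#' Predict with a CNN-ATT model, returning attention scores
#'
#' @param model a `"trained_cnn"` from [cnn_att_fit()].
#' @param X N x Ch matrix.
#' @inheritParams predict_cnn
#' @return list with `labels`, `probs` and `att_score` (N x Ch
#'   sample-dependent attention vectors).
#' @export
cnn_att_predict <- function(model, X, checkpoint = c("best", "final")) {
  predict_cnn(model, X, checkpoint = match.arg(checkpoint))
}

#' Accuracy and confusion matrix of predictions
#'
#' @param predicted,truth integer label vectors (0-based).
#' @param q number of classes (defaults to the labels present).
#' @return list with `accuracy` and `confusion` (q x q matrix, rows =
#'   true class, columns = predicted class).
#' @export
evaluate_predictions <- function(predicted, truth, q = NULL) {
  if (length(predicted) != length(truth))
    abort_validation("predicted and truth differ in length")
  q <- as.integer(q %||% (max(predicted, truth) + 1L))
  lv <- 0:(q - 1L)
  cm <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  list(accuracy = mean(predicted == truth), confusion = cm)
}
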