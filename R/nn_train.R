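#' Training configuration for the CNN models
#'
#' Defaults follow the reference training recipe for kernel-spectra
#' classification: Adam, 500 epochs, a stepped learning rate starting at
#' 5e-4 that is multiplied by 0.1 every 100 epochs, and (for the embedded
#' selector) sparsity weight `lambda_penalty = 0.1`.
#'
#' @param epochs number of epochs (>= 1).
#' @param base_lr initial learning rate.
#' @param lr_period epochs between learning-rate steps.
#' @param lr_decay multiplicative decay per step, in (0, 1].
#' @param lambda_penalty L1 weight on the selection-layer scores (used by
#'   the CNN-FS loss only).
#' @param batch_size minibatch size.
#' @param seed integer seed driving parameter initialization and epoch
#'   shuffling; training is deterministic given the seed.
#' @return a `"train_config"` list.
#' @export
train_config <- function(epochs = 500L, base_lr = 5e-4, lr_period = 100L,
                         lr_decay = 0.1, lambda_penalty = 0.1,
                         batch_size = 256L, seed = 1L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) abort_validation("epochs must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1)
    abort_validation("lr_decay must be in (0, 1]")
  if (lambda_penalty < 0) abort_validation("lambda_penalty must be >= 0")
  structure(list(epochs = epochs, base_lr = base_lr,
                 lr_period = as.integer(lr_period), lr_decay = lr_decay,
                 lambda_penalty = lambda_penalty,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stepped learning rate
#'
#' `base_lr * lr_decay^floor(epoch / lr_period)` for a 0-based epoch index:
#' 5e-4 for epochs 0-99, 5e-5 for 100-199, and so on under the defaults.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(epoch < 0) || any(epoch >= cfg$epochs))
    abort_validation("epoch must lie in [0, ", cfg$epochs, ")")
  cfg$base_lr * cfg$lr_decay^(floor(epoch / cfg$lr_period))
}

#' Cross-entropy classification loss
#'
#' Mean over samples of `-sum_j y_ij log(yhat_ij)`, with the log argument
#' clamped at 1e-12 for numerical stability.
#'
#' @param y one-hot N x q matrix of true labels.
#' @param y_hat N x q matrix of predicted class probabilities.
#' @export
ce_loss <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat)))
    abort_validation("y and y_hat shapes differ")
  -mean(rowSums(y * log(pmax(y_hat, 1e-12))))
}

#' Sparsity-penalized selection loss
#'
#' The embedded-selector objective: cross-entropy plus
#' `lambda * sum_j |W_j|` over the selection-layer weights (the ReLU of an
#' absolute value is the absolute value itself). With `lambda = 0` this is
#' exactly [ce_loss()].
#'
#' @inheritParams ce_loss
#' @param state a [sl_state()] (or list with `weights`).
#' @param lambda_penalty nonnegative sparsity weight.
#' @export
fs_loss <- function(y, y_hat, state, lambda_penalty) {
  if (lambda_penalty < 0) abort_validation("lambda_penalty must be >= 0")
  ce_loss(y, y_hat) + lambda_penalty * sum(relu(abs(state$weights)))
}

#' Build a 1-D CNN classifier
#'
#' Architecture: an optional gating head (`"sl"` = trainable selection
#' layer, `"att"` = attention block, `"none"` = plain classifier), then
#' three convolution blocks (16 kernels, size 3, stride 1, same padding;
#' each block is conv -> batch norm -> ELU -> max-pool 2/2), a flatten, and
#' dense layers of 512, 128 and `q` units with ELU between and softmax on
#' top. Needs `ch >= 8` so three pool-by-2 stages keep at least one
#' position.
#'
#' @param ch input channel count.
#' @param q number of classes.
#' @param head `"none"`, `"sl"` or `"att"`.
#' @param nn_units bottleneck width of the attention head.
#' @param conv_filters,kernel_size,dense_units backbone hyperparameters.
#' @return a `"cnn_model"` list (layers + architecture metadata). Weights
#'   are drawn from the current RNG stream (Glorot uniform), except the
#'   selection layer which always starts at all ones.
#' @export
build_cnn <- function(ch, q, head = c("none", "sl", "att"), nn_units = 64L,
                      conv_filters = 16L, kernel_size = 3L,
                      dense_units = c(512L, 128L)) {
  head <- match.arg(head)
  ch <- as.integer(ch); q <- as.integer(q)
  if (ch < 8L)
    abort_validation("ch must be >= 8 (three pooling stages), got ", ch)
  if (kernel_size %% 2L == 0L)
    abort_validation("kernel_size must be odd for same padding")
  layers <- list()
  if (head == "sl") {
    st <- sl_state(ch)
    layers[[length(layers) + 1L]] <-
      list(type = "sl", name = "sl", weights = st$weights)
  } else if (head == "att") {
    st <- att_state(ch, nn_units)
    layers[[length(layers) + 1L]] <-
      c(list(type = "att", name = "att"), st)
  }
  layers[[length(layers) + 1L]] <- list(type = "reshape", name = "reshape")
  L <- ch; cin <- 1L
  for (i in 1:3) {
    layers[[length(layers) + 1L]] <- list(
      type = "conv", name = paste0("conv", i), cin = cin,
      cout = conv_filters, ks = as.integer(kernel_size),
      pad = (as.integer(kernel_size) - 1L) %/% 2L,
      W = glorot_uniform(conv_filters, cin * kernel_size,
                         cin * kernel_size, conv_filters * kernel_size),
      b = rep(0, conv_filters), idxenv = new.env(parent = emptyenv()))
    layers[[length(layers) + 1L]] <- list(
      type = "bn", name = paste0("bn", i), gamma = rep(1, conv_filters),
      beta = rep(0, conv_filters), running_mean = rep(0, conv_filters),
      running_var = rep(1, conv_filters), momentum = 0.9, eps = 1e-5)
    layers[[length(layers) + 1L]] <- list(type = "elu",
                                          name = paste0("elu", i))
    layers[[length(layers) + 1L]] <- list(type = "pool",
                                          name = paste0("pool", i))
    cin <- conv_filters
    L <- L %/% 2L
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten", name = "flatten")
  units <- c(conv_filters * L, dense_units, q)
  for (i in seq_len(length(units) - 1L)) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = paste0("dense", i),
      W = glorot_uniform(units[i + 1L], units[i], units[i], units[i + 1L]),
      b = rep(0, units[i + 1L]))
    if (i < length(units) - 1L)
      layers[[length(layers) + 1L]] <- list(type = "elu",
                                            name = paste0("delu", i))
  }
  structure(list(layers = layers, ch = ch, q = q, head = head,
                 flat_len = conv_filters * L, nn_units = nn_units),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> head=", x$head, ", ch=", x$ch, ", q=", x$q,
      ", flatten=", x$flat_len, "\n", sep = "")
  invisible(x)
}

#' Forward pass of a CNN model
#'
#' @param model a `"cnn_model"`.
#' @param X numeric N x Ch matrix.
#' @param training use batch statistics in batch norm (TRUE) or running
#'   statistics (FALSE, the default inference mode).
#' @return list with `probs` (N x q class probabilities, rows sum to 1),
#'   `logits`, `caches` (per-layer), and `att_score` (N x Ch, attention
#'   head only).
#' @export
cnn_forward <- function(model, X, training = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$ch)
    abort_validation("X has ", ncol(X), " channels; model expects ", model$ch)
  caches <- vector("list", length(model$layers))
  att_score <- NULL
  x <- X
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
    if (model$layers[[i]]$type == "att") att_score <- fw$cache$S
  }
  probs <- softmax_cols(x)  # x: q x N logits
  list(probs = t(probs), logits = t(x), caches = caches,
       att_score = att_score)
}

cnn_backward <- function(model, caches, dlogits_qn) {
  grads <- vector("list", length(model$layers))
  dy <- dlogits_qn
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], dy, caches[[i]])
    grads[i] <- list(bw$grads)
    dy <- bw$dx
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- intersect(names(l), c("weights", "W", "b", "W1", "b1", "W2", "b2",
                                "gamma", "beta"))
    st <- lapply(pn, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- pn
    st
  })
}

adam_step <- function(model, grads, opt, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      m <- b1 * opt[[i]][[p]]$m + (1 - b1) * g[[p]]
      v <- b2 * opt[[i]][[p]]$v + (1 - b2) * g[[p]]^2
      opt[[i]][[p]]$m <- m
      opt[[i]][[p]]$v <- v
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(model = model, opt = opt)
}

update_bn_running <- function(model, caches) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "bn" && isTRUE(caches[[i]]$training)) {
      mom <- l$momentum
      model$layers[[i]]$running_mean <- mom * l$running_mean +
        (1 - mom) * caches[[i]]$mu
      model$layers[[i]]$running_var <- mom * l$running_var +
        (1 - mom) * caches[[i]]$v
    }
  }
  model
}

one_hot <- function(labels, q) {
  Y <- matrix(0, q, length(labels))
  Y[cbind(labels + 1L, seq_along(labels))] <- 1
  Y
}

split_cal_val <- function(data) {
  if (inherits(data, "spectra_matrix")) {
    if (is.null(data$splits))
      abort_validation("spectra matrix needs cal/val splits for training")
    list(cal = sm_subset(data, split = "cal"),
         val = sm_subset(data, split = "val"))
  } else if (is.list(data) && !is.null(data$cal) && !is.null(data$val)) {
    data
  } else abort_validation("data must be a split spectra_matrix or ",
                          "list(cal=, val=)")
}

#' Train a CNN (plain, selection-layer or attention variant)
#'
#' Minimizes cross-entropy (plus the L1 selection penalty when
#' `head = "sl"`) with Adam under the stepped learning-rate schedule.
#' A single seed in `cfg` drives initialization and shuffling, so two runs
#' with the same inputs are identical. Per epoch the calibration loss,
#' validation accuracy and learning rate are recorded; the parameter state
#' at the best validation accuracy is checkpointed.
#'
#' @param data a `"spectra_matrix"` with cal/val splits, or
#'   `list(cal=, val=)` of spectra matrices.
#' @param head `"none"`, `"sl"` (CNN-FS) or `"att"` (CNN-ATT).
#' @param cfg a [train_config()].
#' @param nn_units attention bottleneck width (`head = "att"`).
#' @return a `"trained_cnn"`: list with `model` (final), `best_model`,
#'   `best_epoch`, `best_val_accuracy`, `history` (data.frame epoch, loss,
#'   val_accuracy, lr), `cfg`.
#' @export
train_cnn <- function(data, head = c("none", "sl", "att"),
                      cfg = train_config(), nn_units = 64L) {
  head <- match.arg(head)
  stopifnot(inherits(cfg, "train_config"))
  d <- split_cal_val(data)
  cal <- d$cal; val <- d$val
  q <- max(cal$labels, val$labels) + 1L
  ch <- ncol(cal$X)
  n <- nrow(cal$X)
  lambda <- if (head == "sl") cfg$lambda_penalty else 0
  with_seed(cfg$seed, {
    model <- build_cnn(ch, q, head = head, nn_units = nn_units)
    opt <- adam_init(model$layers)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_accuracy = numeric(), lr = numeric())
    best <- list(acc = -Inf, model = model, epoch = 0L)
    t <- 0L
    for (epoch in 0:(cfg$epochs - 1L)) {
      lr <- lr_at_epoch(cfg, epoch)
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- idx[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- cal$X[b, , drop = FALSE]
        Yb <- one_hot(cal$labels[b], q)
        fw <- cnn_forward(model, Xb, training = TRUE)
        P <- t(fw$probs)  # q x N
        loss <- -mean(colSums(Yb * log(pmax(P, 1e-12))))
        if (lambda > 0) {
          isl <- which(vapply(model$layers, function(l)
            l$type == "sl", TRUE))[1L]
          loss <- loss + lambda * sum(abs(model$layers[[isl]]$weights))
        }
        if (!is.finite(loss))
          stop_wavesel("training diverged (non-finite loss at epoch ",
                       epoch, "); try a smaller learning rate or check ",
                       "input scaling", class = "wavesel_divergence_error")
        dlogits <- (P - Yb) / length(b)
        grads <- cnn_backward(model, fw$caches, dlogits)
        if (lambda > 0)
          grads[[isl]]$weights <- grads[[isl]]$weights +
            lambda * sign(model$layers[[isl]]$weights)
        model <- update_bn_running(model, fw$caches)
        t <- t + 1L
        up <- adam_step(model, grads, opt, lr, t)
        model <- up$model
        opt <- up$opt
        ep_loss <- ep_loss + loss * length(b)
      }
      ep_loss <- ep_loss / n
      acc <- mean(predict_cnn(model, val$X)$labels == val$labels)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss,
                                     val_accuracy = acc, lr = lr))
      # on ties the later epoch wins: equal accuracy, more settled weights
      if (acc >= best$acc) best <- list(acc = acc, model = model,
                                        epoch = epoch)
    }
    structure(list(model = model, best_model = best$model,
                   best_epoch = best$epoch, best_val_accuracy = best$acc,
                   history = hist, cfg = cfg, head = head),
              class = "trained_cnn")
  })
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat("<trained_cnn> head=", x$head, ", ", nrow(x$history), " epochs, ",
      "best val accuracy ", sprintf("%.4f", x$best_val_accuracy),
      " @ epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict with a CNN model
#'
#' @param model a `"cnn_model"` or `"trained_cnn"` (uses the
#'   best-validation checkpoint).
#' @param X N x Ch matrix.
#' @param batch_size inference batch size (results are independent of the
#'   batching).
#' @param checkpoint for a `"trained_cnn"`: `"best"` (default) or
#'   `"final"`.
#' @return list with `labels` (integer, 0-based), `probs` (N x q) and
#'   `att_score` (N x Ch or NULL).
#' @export
predict_cnn <- function(model, X, batch_size = 1024L,
                        checkpoint = c("best", "final")) {
  checkpoint <- match.arg(checkpoint)
  if (inherits(model, "trained_cnn"))
    model <- if (checkpoint == "best") model$best_model else model$model
  X <- as.matrix(X)
  n <- nrow(X)
  probs <- matrix(0, n, model$q)
  att <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    b <- s:min(s + batch_size - 1L, n)
    fw <- cnn_forward(model, X[b, , drop = FALSE], training = FALSE)
    probs[b, ] <- fw$probs
    if (!is.null(fw$att_score)) {
      if (is.null(att)) att <- matrix(0, n, model$ch)
      att[b, ] <- fw$att_score
    }
  }
  list(labels = max.col(probs) - 1L, probs = probs, att_score = att)
}

#' Selection-layer weights of a model
#'
#' @param x a `"cnn_model"` or `"trained_cnn"` with an `"sl"` head.
#' @param checkpoint `"best"` or `"final"` (for `"trained_cnn"`).
#' @return the raw weight vector W_SL; its ReLU is the score vector.
#' @export
sl_weights <- function(x, checkpoint = c("best", "final")) {
  checkpoint <- match.arg(checkpoint)
  if (inherits(x, "trained_cnn"))
    x <- if (checkpoint == "best") x$best_model else x$model
  i <- which(vapply(x$layers, function(l) l$type == "sl", TRUE))
  if (!length(i)) abort_validation("model has no selection layer")
  x$layers[[i[1L]]]$weights
}
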