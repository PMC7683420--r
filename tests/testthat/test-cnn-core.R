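test_that("relu matches its piecewise definition", {
  expect_identical(relu(3), 3)
  expect_identical(relu(-2), 0)
  expect_identical(relu(0), 0)
  expect_equal(relu(c(-1.5, 0, 2.5)), c(0, 0, 2.5))
})

test_that("selection block is the identity at initialization and gates channels", {
  st <- sl_state(5)
  expect_identical(st$weights, rep(1, 5))
  X <- matrix(rnorm(20, 1, 0.2), 4, 5)
  expect_equal(sl_forward(st, X), X)

  st$weights[3] <- -0.5
  Y <- sl_forward(st, X)
  expect_equal(Y[, 3], rep(0, 4))
  expect_equal(Y[, -3], X[, -3])

  expect_equal(sl_forward(list(weights = 2), matrix(3, 1, 1)),
               matrix(6, 1, 1))
  expect_error(sl_forward(st, matrix(1, 2, 4)),
               class = "wavesel_validation_error")
})

test_that("attention block matches a hand-evaluated forward pass", {
  # zero pre-activation with sigmoid output: every gate is exactly 0.5
  st <- att_state(3, 2)
  st$W1[] <- 0; st$W2[] <- 0; st$b1[] <- 0; st$b2[] <- 0
  X <- matrix(rnorm(12), 4, 3)
  out <- att_forward(st, X)
  expect_equal(out$score, matrix(0.5, 4, 3), ignore_attr = TRUE)
  expect_equal(out$Y, X / 2)

  # nn = 1, two channels: hand-computed tanh/sigmoid arithmetic
  st2 <- att_state(2, 1)
  st2$W1 <- matrix(c(0.5, -0.3), 1, 2); st2$b1 <- 0.2
  st2$W2 <- matrix(c(0.8, -0.6), 2, 1); st2$b2 <- c(0.1, -0.2)
  x <- c(1, 2)
  h <- tanh(0.5 * 1 - 0.3 * 2 + 0.2)
  s_hand <- c(1 / (1 + exp(-(0.8 * h + 0.1))),
              1 / (1 + exp(-(-0.6 * h - 0.2))))
  out2 <- att_forward(st2, matrix(x, 1, 2))
  expect_equal(drop(out2$score), s_hand)
  expect_equal(drop(out2$Y), s_hand * x)

  # gates are sample-dependent
  st3 <- att_state(4, 2)
  two <- att_forward(st3, rbind(rnorm(4, 1), rnorm(4, -1)))
  expect_gt(max(abs(two$score[1, ] - two$score[2, ])), 1e-6)
})

test_that("backbone shape arithmetic and softmax normalization hold", {
  set.seed(2)
  m200 <- build_cnn(200, 30)
  expect_identical(m200$flat_len, 400L)  # 200 -> 100 -> 50 -> 25, x16
  m60 <- build_cnn(60, 30)
  expect_identical(m60$flat_len, 112L)   # 60 -> 30 -> 15 -> 7, x16
  expect_error(build_cnn(7, 3), class = "wavesel_validation_error")

  X <- matrix(rnorm(5 * 60, 1, 0.3), 5, 60)
  for (training in c(TRUE, FALSE)) {
    p <- cnn_forward(m60, X, training = training)$probs
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("cross-entropy and the penalized selection loss follow their formulas", {
  q <- 30
  perfect <- diag(q)[1:4, ]
  expect_equal(ce_loss(perfect, perfect), 0, tolerance = 1e-9)
  uniform <- matrix(1 / q, 4, q)
  expect_equal(ce_loss(perfect, uniform), log(q), tolerance = 1e-9)

  # two-sample hand case
  y <- rbind(c(1, 0, 0), c(0, 0, 1))
  yh <- rbind(c(0.7, 0.2, 0.1), c(0.25, 0.25, 0.5))
  expect_equal(ce_loss(y, yh), -(log(0.7) + log(0.5)) / 2)

  # lambda = 0 reduces exactly to cross-entropy
  set.seed(4)
  for (i in 1:100) {
    yy <- diag(5)[sample(5, 3, TRUE), ]
    p <- matrix(runif(15), 3, 5); p <- p / rowSums(p)
    w <- list(weights = rnorm(8))
    expect_equal(fs_loss(yy, p, w, 0), ce_loss(yy, p), tolerance = 1e-12)
  }

  # 200 unit weights at lambda = 0.1 add exactly 20 to a perfect fit
  ones <- list(weights = rep(1, 200))
  expect_equal(fs_loss(perfect, perfect, ones, 0.1), 20, tolerance = 1e-9)
  # |-1| penalizes the same as |+1|
  mixed <- list(weights = rep(c(1, -1), 100))
  expect_equal(fs_loss(perfect, perfect, mixed, 0.1), 20, tolerance = 1e-9)
  expect_error(fs_loss(perfect, perfect, ones, -0.1),
               class = "wavesel_validation_error")
})

test_that("the stepped learning-rate schedule decays by decades", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 5e-4)
  expect_equal(lr_at_epoch(cfg, 99), 5e-4)
  expect_equal(lr_at_epoch(cfg, 100), 5e-5)
  expect_equal(lr_at_epoch(cfg, 499), 5e-4 * 0.1^4)
  lrs <- lr_at_epoch(cfg, 0:499)
  expect_true(all(diff(lrs) <= 0))
  expect_identical(length(unique(lrs)), 5L)
  expect_error(lr_at_epoch(cfg, 500), class = "wavesel_validation_error")
  expect_error(lr_at_epoch(cfg, -1), class = "wavesel_validation_error")
})

test_that("analytic selection-layer gradient matches finite differences", {
  set.seed(8)
  q <- 2; N <- 6
  model <- build_cnn(8, q, head = "sl")
  model$layers[[1]]$weights <- runif(8, 0.3, 1.4)
  X <- matrix(rnorm(N * 8, 1, 0.4), N, 8)
  Y <- one_hot(sample(0:(q - 1), N, TRUE), q)
  lambda <- 0.1

  loss_at <- function(w) {
    m <- model; m$layers[[1]]$weights <- w
    fw <- cnn_forward(m, X, training = TRUE)
    fs_loss(t(Y), fw$probs, list(weights = w), lambda)
  }
  fw <- cnn_forward(model, X, training = TRUE)
  grads <- wavesel:::cnn_backward(model, fw$caches, (t(fw$probs) - Y) / N)
  ana <- grads[[1]]$weights + lambda * sign(model$layers[[1]]$weights)
  w0 <- model$layers[[1]]$weights
  eps <- 1e-6
  num <- vapply(seq_along(w0), function(k) {
    wp <- w0; wp[k] <- wp[k] + eps
    wm <- w0; wm[k] <- wm[k] - eps
    (loss_at(wp) - loss_at(wm)) / (2 * eps)
  }, 0)
  rel <- abs(num - ana) / pmax(abs(num) + abs(ana), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("training is deterministic, learns a separable task, and reacts to lambda", {
  gen <- easy_gen()
  cfg <- train_config(epochs = 30, batch_size = 64, seed = 5)
  t1 <- train_cnn(gen$sm, head = "att", cfg = cfg, nn_units = 16)
  expect_equal(t1$best_val_accuracy, 1)
  expect_identical(nrow(t1$history), 30L)
  expect_true(all(c("loss", "val_accuracy", "lr") %in% names(t1$history)))

  t2 <- train_cnn(gen$sm, head = "att", cfg = cfg, nn_units = 16)
  expect_lt(abs(tail(t1$history$loss, 1) - tail(t2$history$loss, 1)), 1e-6)
  expect_identical(predict_cnn(t1, gen$sm$X[1:10, ])$labels,
                   predict_cnn(t2, gen$sm$X[1:10, ])$labels)

  # selection scores stay nonnegative; a huge lambda crushes them
  cfg_sl <- train_config(epochs = 15, batch_size = 64, seed = 5,
                         lambda_penalty = 0.1)
  s_small <- train_cnn(gen$sm, head = "sl", cfg = cfg_sl)
  sc <- relu(sl_weights(s_small, "final"))
  expect_true(all(sc >= 0))
  cfg_big <- train_config(epochs = 15, batch_size = 64, seed = 5,
                          lambda_penalty = 1000)
  s_big <- train_cnn(gen$sm, head = "sl", cfg = cfg_big)
  expect_lt(sum(relu(sl_weights(s_big, "final"))), sum(sc))
})
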