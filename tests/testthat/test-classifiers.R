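test_that("PLSDA at full rank matches the least-squares argmax oracle", {
  set.seed(9)
  n <- 40; p <- 5; q <- 3
  X <- matrix(rnorm(n * p), n, p)
  beta <- matrix(rnorm(p * q), p, q)
  y <- max.col(X %*% beta + 0.1 * matrix(rnorm(n * q), n, q)) - 1L
  sm <- spectra_matrix(X, y, seq_len(p) * 100 + 900)

  m <- plsda_fit(sm, comp = p)
  got <- plsda_predict(m, X)

  Y <- sapply(0:(q - 1), function(k) as.numeric(y == k))
  ols <- stats::lm.fit(cbind(1, X), Y)
  oracle <- max.col(cbind(1, X) %*% ols$coefficients) - 1L
  expect_identical(got, oracle)
})

test_that("PLSDA separates a one-informative-channel toy with one component", {
  set.seed(10)
  n <- 30
  y <- rep(0:1, each = n / 2)
  X <- cbind(ifelse(y == 0, -1, 1) + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 3, 0, 0.1), n, 3))
  sm <- spectra_matrix(X, y, c(1000, 1100, 1200, 1300))
  m <- plsda_fit(sm, comp = 1)
  expect_equal(mean(plsda_predict(m, X) == y), 1)

  # memorizable toy at comp = N - 1
  set.seed(12)
  Xs <- matrix(rnorm(8 * 10), 8, 10)
  ys <- c(0, 1, 2, 3, 0, 1, 2, 3)
  sms <- spectra_matrix(Xs, ys, seq_len(10))
  msat <- suppressWarnings(plsda_fit(sms, comp = 7))
  expect_equal(mean(plsda_predict(msat, Xs) == ys), 1)
})

test_that("PLSDA component search is exhaustive with smallest-comp ties", {
  set.seed(14)
  n <- 60; p <- 8
  y <- sample(0:2, n, TRUE)
  # rank-2 signal: the validation curve must be flat beyond comp = 2
  basis <- matrix(rnorm(2 * p), 2, p)
  scores2 <- cbind(y == 0, y == 1) + matrix(rnorm(n * 2, 0, 0.05), n, 2)
  X <- scores2 %*% basis
  sm <- spectra_matrix(X, y, seq_len(p), splits = rep(c("cal", "val"),
                                                      length.out = n))
  out <- plsda_select_comp(sm, comp_range = 1:6)
  expect_lte(nrow(out$curve), 6)
  expect_equal(out$best_accuracy, max(out$curve$val_accuracy))
  expect_identical(out$best_comp,
                   out$curve$comp[which.max(out$curve$val_accuracy)])
  flat <- out$curve$val_accuracy[out$curve$comp >= 2]
  expect_lt(diff(range(flat)), 1e-9)
})

test_that("PLSDA agrees with an independent PLS implementation at one component", {
  set.seed(15)
  n <- 50; p <- 6
  y <- rep(0:1, each = 25)
  X <- matrix(rnorm(n * p), n, p) + outer(ifelse(y == 1, 1, -1), rep(0.5, p))
  colnames(X) <- paste0("ch", seq_len(p))
  sm <- spectra_matrix(X, y, seq_len(p))
  mine <- plsda_predict(plsda_fit(sm, comp = 1), X)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 1, scale = FALSE)
  refp <- as.integer(as.character(
    predict(ref, X, dist = "max.dist")$class$max.dist[, 1]))
  expect_identical(mine, refp)
})

test_that("RBF-SVC grid search is exhaustive and prefers small parameters on ties", {
  gen <- easy_gen()
  sm <- gen$sm
  Cg <- 10^(0:2); gg <- 10^(-2:0)
  gs <- rbf_svc_grid_search(sm, C_grid = Cg, gamma_grid = gg)
  expect_identical(nrow(gs$surface), length(Cg) * length(gg))
  expect_equal(gs$best$val_accuracy, max(gs$surface$val_accuracy))
  # easy preset: everything separates, so ties resolve to the smallest pair
  expect_equal(gs$best$C, min(Cg))
  expect_equal(gs$best$gamma,
               min(gs$surface$gamma[gs$surface$C == gs$best$C &
                                      gs$surface$val_accuracy ==
                                      gs$best$val_accuracy]))
})

test_that("RBF-SVC solves a concentric-rings problem no linear model can", {
  set.seed(16)
  n <- 200
  r <- c(runif(n / 2, 0, 0.5), runif(n / 2, 1, 1.5))
  th <- runif(n, 0, 2 * pi)
  X <- cbind(r * cos(th), r * sin(th)) + 2  # keep features positive
  y <- rep(0:1, each = n / 2)
  idx <- sample(n)
  sm <- spectra_matrix(X[idx, ], y[idx], c(1000, 1100),
                       splits = rep(c("cal", "val"), length.out = n))
  gs <- rbf_svc_grid_search(sm, C_grid = 10^(0:4), gamma_grid = 10^(-2:2))
  expect_gte(gs$best$val_accuracy, 0.95)
  expect_lt(ols_argmax_accuracy(sm_subset(sm, split = "cal"),
                                sm_subset(sm, split = "val")), 0.8)
})

test_that("CNN-ATT learns a separable task and predicts batch-invariantly", {
  gen <- easy_gen()
  fit <- cnn_att_fit(gen$sm, nn_units = 16,
                     cfg = train_config(epochs = 30, batch_size = 64,
                                        seed = 6))
  expect_equal(fit$best_val_accuracy, 1)

  pre <- sm_subset(gen$sm, split = "pre")
  whole <- cnn_att_predict(fit, pre$X)
  expect_equal(rowSums(whole$probs), rep(1, nrow(pre$X)), tolerance = 1e-6)
  # attention vectors vary with the sample
  expect_gt(max(abs(whole$att_score[1, ] - whole$att_score[2, ])), 1e-8)

  # batching must not change predictions
  single <- predict_cnn(fit, pre$X, batch_size = 7L)
  expect_identical(whole$labels, single$labels)
  expect_lt(max(abs(whole$probs - single$probs)), 1e-6)

  fit2 <- cnn_att_fit(gen$sm, nn_units = 16,
                      cfg = train_config(epochs = 30, batch_size = 64,
                                         seed = 6))
  expect_lt(abs(tail(fit$history$loss, 1) - tail(fit2$history$loss, 1)),
            1e-6)
})

test_that("evaluation reports accuracy and a conserving confusion matrix", {
  truth <- c(0, 0, 1, 1, 2, 2)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(diag(perfect$confusion)), c(2, 2, 2))
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  pred <- c(0, 1, 1, 2, 2, 2)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(rowSums(ev$confusion)), c(2, 2, 2))
  expect_equal(sum(ev$confusion), 6)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 6)
})
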