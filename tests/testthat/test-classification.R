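# classification: the SMO solver against a frozen libsvm oracle, grid-search
# training, determinism, and majority-vote decoding.

test_that("the SMO solver matches libsvm decision values on a fixed problem", {
  # Oracle frozen from scikit-learn SVC (libsvm backend), C = 2, gamma = 0.5,
  # on this exact seeded dataset.
  set.seed(42)
  X <- matrix(round(rnorm(40), 6), 20, 2)
  y <- rep(c(1, -1), each = 10)
  X[y == 1, 1] <- X[y == 1, 1] + 1.2
  K <- fricshape:::cpp_rbf_kernel(X, X, 0.5)
  sol <- fricshape:::cpp_smo(K, y, C = 2)
  f <- as.numeric(K %*% (sol$alpha * y)) - sol$rho
  expect_equal(sol$rho, 0.06910246, tolerance = 2e-2)
  expect_equal(f[1:6],
               c(1.000032, 0.561711, 0.625945, 0.459456, 0.999667, 0.702889),
               tolerance = 2e-3)
  # dual feasibility
  expect_true(all(sol$alpha >= 0 & sol$alpha <= 2 + 1e-12))
  expect_equal(sum(sol$alpha * y), 0, tolerance = 1e-10)
})

test_that("separable blobs reach 100% CV and training accuracy", {
  blobs <- make_blobs(n_per = 15, sep = 10, seed = 2)
  model <- train_svm(blobs$X, blobs$y, small_grid(seed = 3))
  expect_equal(model$cv_accuracy, 1)
  pred <- predict(model, blobs$X)
  expect_equal(as.character(pred$labels), as.character(blobs$y))
})

test_that("shuffled labels yield chance-level CV accuracy", {
  blobs <- make_blobs(n_per = 30, sep = 10, seed = 4)
  set.seed(5)
  y_shuf <- sample(blobs$y)
  model <- train_svm(blobs$X, y_shuf, small_grid(seed = 6))
  expect_lt(abs(model$cv_accuracy - 1 / 3), 0.17)
})

test_that("grid search is deterministic and breaks ties toward small C then gamma", {
  blobs <- make_blobs(n_per = 12, sep = 9, seed = 7)
  m1 <- train_svm(blobs$X, blobs$y, small_grid(seed = 8))
  m2 <- train_svm(blobs$X, blobs$y, small_grid(seed = 8))
  expect_identical(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
  # on separable blobs several grid points reach 100%; the smallest C (and
  # then smallest gamma) among the maximizers must be chosen
  best <- m1$cv_table[m1$cv_table$accuracy == max(m1$cv_table$accuracy), ]
  expect_equal(m1$C, min(best$C))
  expect_equal(m1$gamma, min(best$gamma[best$C == m1$C]))
})

test_that("training validates labels and degenerate features", {
  blobs <- make_blobs(n_per = 10, seed = 9)
  expect_error(train_svm(blobs$X[1:20, ], blobs$y[1:20], small_grid()),
               "class")
  expect_error(train_svm(matrix(1, 30, 2), blobs$y, small_grid()),
               "degenerate")
})

test_that("standardization gives per-dimension mean 0 and variance 1", {
  blobs <- make_blobs(n_per = 15, seed = 10)
  model <- train_svm(blobs$X, blobs$y, small_grid(seed = 1))
  Xs <- fricshape:::scale_apply(model$scaler, blobs$X)
  expect_equal(colMeans(Xs), rep(0, 2), tolerance = 1e-9)
  expect_equal(apply(Xs, 2, stats::sd), rep(1, 2), tolerance = 1e-9)
})

test_that("build_training_set yields 2 seeded rows per token", {
  corp <- generate_corpus(cs = small_corpus_spec(seed = 11, n = 6))
  ts1 <- build_training_set(corp$train, "gt14", seed = 12)
  ts2 <- build_training_set(corp$train, "gt14", seed = 12)
  expect_equal(nrow(ts1$features), 2 * length(corp$train))
  expect_equal(ncol(ts1$features), 14)
  counts <- table(ts1$labels)
  expect_true(all(counts == 12))    # 2 x 6 tokens per group
  expect_identical(ts1$features, ts2$features)
  ts3 <- build_training_set(corp$train, "gt14", seed = 13)
  expect_false(identical(ts1$features, ts3$features))
})

test_that("majority vote decodes tokens and ignores frame order", {
  corp <- generate_corpus(cs = small_corpus_spec(seed = 14, n = 8))
  ts <- build_training_set(corp$train, "gt14", seed = 15)
  model <- train_svm(ts$features, ts$labels, small_grid(seed = 16),
                     feature_set = "gt14")
  res <- classify_token(model, corp$test[[1]])
  expect_true(as.character(res$group) %in% FRIC_GROUPS)
  expect_equal(as.character(res$group),
               names(which.max(table(res$frame_labels)))[1])

  # permuting the frames of a token cannot change the majority label
  tok <- corp$test[[2]]
  L <- 128
  k <- length(tok$samples) %/% L
  set.seed(17)
  perm <- sample(k)
  shuffled <- tok
  shuffled$samples <- as.numeric(matrix(tok$samples[1:(k * L)], L)[, perm])
  r1 <- classify_token(model, tok)
  r2 <- classify_token(model, shuffled)
  expect_equal(sort(as.character(r1$frame_labels)),
               sort(as.character(r2$frame_labels)))
  expect_equal(as.character(r1$group), as.character(r2$group))

  expect_error(predict(model, matrix(0, 2, 3)), "dimension")
})
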