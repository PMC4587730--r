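test_that("one-vs-one builds K(K-1)/2 pairwise classifiers", {
  b7 <- make_blobs(K = 7, n_per = 8, d = 5, seed = 4)
  fit <- fit_ovo(b7$X, b7$y, C = 10, classes = b7$classes)
  expect_equal(fit$n_pairs, 21L)

  b2 <- make_blobs(K = 2, n_per = 8, seed = 4)
  fit2 <- fit_ovo(b2$X, b2$y, C = 10, classes = b2$classes)
  expect_equal(fit2$n_pairs, 1L)
  pr2 <- predict_votes_dv(fit2, b2$X)
  expect_true(all(vapply(pr2$votes, sum, 1) == 1))

  expect_error(fit_ovo(b2$X[1:8, ], b2$y[1:8], C = 1), "2 classes")
})

test_that("votes are conserved and match the predicted class argmax", {
  b <- make_blobs(K = 7, n_per = 8, d = 5, seed = 6)
  fit <- fit_ovo(b$X, b$y, C = 10, classes = b$classes)
  pr <- predict_votes_dv(fit, b$X)
  expect_true(all(vapply(pr$votes, sum, 1) == 21))
  argmax <- vapply(pr$votes, function(v) b$classes[which.max(v)], "")
  expect_identical(pr$predicted, argmax)
  # my vote reconstruction agrees with libsvm's own label prediction
  raw <- as.character(predict(fit$model, scale(b$X,
    center = fit$scaler$mean, scale = fit$scaler$sd)))
  expect_identical(pr$predicted, raw)
})

test_that("separable data: perfect training accuracy and K-1 votes deep in-class", {
  b <- make_blobs(K = 4, n_per = 10, d = 4, spread = 10, sd = 0.3, seed = 9)
  fit <- fit_ovo(b$X, b$y, C = 1000, classes = b$classes)
  pr <- predict_votes_dv(fit, b$X)
  expect_equal(mean(pr$predicted == b$y), 1)
  # the first item sits deep inside class c1's region
  expect_equal(unname(pr$votes[[1]]["c1"]), 3L)
})

test_that("pairwise decision-value sign favors the lower-indexed class", {
  b <- make_blobs(K = 2, n_per = 12, spread = 8, seed = 12)
  fit <- fit_ovo(b$X, b$y, C = 100, classes = b$classes)
  pr <- predict_votes_dv(fit, b$X)
  dv12 <- vapply(pr$dv, `[[`, 1, "1/2")
  expect_true(all(dv12[pr$predicted == "c1"] > 0))
  expect_true(all(dv12[pr$predicted == "c2"] < 0))
})

test_that("training is deterministic for identical inputs", {
  b <- make_blobs(K = 3, n_per = 10, seed = 14)
  f1 <- fit_ovo(b$X, b$y, C = 5, gamma = 0.1, classes = b$classes)
  f2 <- fit_ovo(b$X, b$y, C = 5, gamma = 0.1, classes = b$classes)
  expect_identical(predict_votes_dv(f1, b$X), predict_votes_dv(f2, b$X))
})

test_that("standardization uses training statistics only", {
  b <- make_blobs(K = 3, n_per = 10, seed = 15)
  train <- b$X[1:24, ]
  fit <- fit_ovo(train, b$y[1:24], C = 1, classes = b$classes)
  expect_equal(fit$scaler$mean, colMeans(train))
  expect_equal(fit$scaler$sd, apply(train, 2, sd))
  # predicting on new data must not change the stored scaler
  invisible(predict_votes_dv(fit, b$X[25:30, ]))
  expect_equal(fit$scaler$mean, colMeans(train))
  fit_ns <- fit_ovo(train, b$y[1:24], C = 1, standardize = FALSE)
  expect_null(fit_ns$scaler)
})

test_that("grid search returns the best point with smallest-C/gamma ties", {
  b <- make_blobs(K = 3, n_per = 10, spread = 10, sd = 0.3, seed = 18)
  cfg <- svm_config(C_grid = c(1, 100), gamma_grid = c(0.01, 1),
                    n_folds = 3, seed = 2)
  tu <- tune_hyperparameters(b$X, b$y, cfg)
  expect_equal(tu$cv_accuracy, 1) # separable blobs reach CV accuracy 1
  # exhaustive oracle: re-evaluate every grid point with the same folds
  fold <- withr::with_seed(2, protnoise:::stratified_folds(b$y, 3))
  oracle <- apply(as.matrix(tu$grid[, c("C", "gamma")]), 1, function(p) {
    mean(vapply(1:3, function(f) {
      fit <- fit_ovo(b$X[fold != f, ], b$y[fold != f], C = p[1],
                     gamma = p[2], classes = unique(b$y))
      mean(predict_votes_dv(fit, b$X[fold == f, ])$predicted ==
             b$y[fold == f])
    }, 1))
  })
  expect_equal(tu$grid$cv_accuracy, unname(oracle))
  best <- which(oracle == max(oracle))
  expect_equal(c(tu$C_opt, tu$gamma_opt),
               unname(unlist(tu$grid[best[1], c("C", "gamma")])))

  single <- tune_hyperparameters(b$X, b$y,
    svm_config(C_grid = 4, gamma_grid = 0.25, n_folds = 3, seed = 2))
  expect_equal(c(single$C_opt, single$gamma_opt), c(4, 0.25))

  expect_error(
    tune_hyperparameters(b$X[1:11, ], b$y[1:11],
                         svm_config(n_folds = 5, seed = 1)),
    "fewer")
})
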