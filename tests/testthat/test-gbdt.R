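# well-separated K-class Gaussian blobs
blob_data <- function(n = 100, K = 2, d = 10, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep_len(0:(K - 1), n)
  centers <- matrix(rnorm(K * d), K) * sep
  X <- centers[y + 1, ] + matrix(rnorm(n * d), n)
  list(X = X, y = label_vector(paste0("s", 1:n), y,
                               class_names = paste0("c", 1:K)))
}

test_that("the configuration enforces its invariants", {
  cfg <- gbdt_config()
  expect_equal(cfg$learning_rate, 0.1)
  expect_equal(cfg$n_estimators, 300L)
  expect_equal(cfg$max_depth, 3L)
  expect_equal(cfg$min_samples_leaf, 5L)
  expect_equal(cfg$subsample, 0.8)
  expect_error(gbdt_config(n_estimators = 301), "cap")
  expect_error(gbdt_config(learning_rate = 0), "learning_rate")
  expect_error(gbdt_config(subsample = 1.2), "subsample")
  expect_error(gbdt_config(loss = "exponential"), "deviance")
})

test_that("separable classes are fit to perfect training accuracy", {
  d <- blob_data(n = 100, K = 2, seed = 2)
  fit <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 60, seed = 1))
  pred <- predict(fit, d$X)
  expect_equal(evaluate(d$y, pred$labels)$accuracy, 100)
  # probability rows sum to one
  expect_lt(max(abs(rowSums(pred$prob) - 1)), 1e-9)
})

test_that("one-vs-all builds M x K trees honoring the depth/leaf limits", {
  d <- blob_data(n = 120, K = 4, d = 8, seed = 3)
  fit <- fit_gbdt(d$X, d$y, gbdt_config(seed = 1)) # M = 300, K = 4
  expect_equal(sum(fit$n_trees), 1200L)
  for (bst in fit$boosters) {
    tr <- xgboost::xgb.model.dt.tree(model = bst)
    expect_equal(max(tr$Tree) + 1L, 300L)
    # depth <= 3: node ids within a tree never exceed depth-3 breadth
    depth <- floor(log2(tr$Node + 1))
    expect_lte(max(depth), 3L)
    # every leaf carries hessian cover >= 1.25, i.e. >= 5 samples under
    # the binary-logistic hessian bound of 0.25 per sample
    expect_gte(min(tr$Cover[tr$Feature == "Leaf"]), 1.25)
  }
})

test_that("staged training loss descends stage by stage", {
  d <- blob_data(n = 80, K = 3, d = 6, seed = 4)
  # without row subsampling every stage is a descent step on the full
  # training loss (the forward-stagewise guarantee)
  fit1 <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 120, seed = 2,
                                         subsample = 1))
  expect_length(fit1$staged_train_loss, 120L)
  # the engine reports the staged metric in single precision, so
  # monotonicity is asserted to float32 resolution
  expect_true(all(diff(fit1$staged_train_loss) <= 1e-6))
  # with the stochastic 0.8 subsample the guarantee is in expectation
  # only: require overall descent
  fit <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 120, seed = 2))
  expect_lt(fit$staged_train_loss[120], fit$staged_train_loss[1])
})

test_that("degenerate labels and widths raise the documented errors", {
  d <- blob_data(n = 30, K = 2, seed = 5)
  one_class <- label_vector(d$y$sample_ids, rep(0L, 30),
                            class_names = "only")
  expect_error(fit_gbdt(d$X, one_class, gbdt_config()), "single class")
  fit <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 5, seed = 1))
  expect_error(predict(fit, d$X[, 1:3]), "width")
  tiny <- blob_data(n = 12, K = 4, seed = 6)
  expect_warning(fit_gbdt(tiny$X, tiny$y,
                          gbdt_config(n_estimators = 5, seed = 1)),
                 "fewer samples than min_samples_leaf")
})

test_that("vanishing learning rate shrinks predictions to the prior", {
  d <- blob_data(n = 90, K = 3, d = 6, seed = 7)
  fit <- fit_gbdt(d$X, d$y, gbdt_config(learning_rate = 1e-4,
                                        n_estimators = 10, seed = 1))
  pred <- predict(fit, d$X)
  # balanced classes: probabilities collapse to ~1/3 everywhere
  expect_lt(max(abs(pred$prob - 1 / 3)), 0.01)
})

test_that("early stopping halts before the estimator cap on noise", {
  set.seed(8)
  X <- matrix(rnorm(120 * 5), 120)
  y <- label_vector(paste0("s", 1:120), rep_len(0:1, 120),
                    class_names = c("a", "b"))
  fit <- fit_gbdt(X, y, gbdt_config(
    seed = 3, early_stopping = list(validation_fraction = 0.2,
                                    patience = 5)))
  expect_true(all(fit$n_trees < 300L))
})

test_that("fitting is deterministic in the configured seed", {
  d <- blob_data(n = 60, K = 2, seed = 9)
  f1 <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 40, seed = 7))
  f2 <- fit_gbdt(d$X, d$y, gbdt_config(n_estimators = 40, seed = 7))
  expect_identical(f1$staged_train_loss, f2$staged_train_loss)
  expect_identical(predict(f1, d$X)$prob, predict(f2, d$X)$prob)
})

test_that("evaluate reports accuracy and macro-averaged P/R/F1", {
  perfect <- evaluate(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  r <- evaluate(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(r$accuracy, 75.0)
  expect_equal(r$precision, 83.3) # mean(1, 2/3)
  expect_equal(r$recall, 75.0)    # mean(1/2, 1)
  expect_equal(r$f1, 73.3)        # mean(2/3, 4/5)
  expect_equal(unname(r$confusion), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(sum(r$confusion), r$n)
  expect_error(evaluate(c(0, 1), c(0, 5)), "outside")
})

test_that("chance-level predictions score near 1/K accuracy", {
  set.seed(10)
  n <- 4000
  y <- sample(0:3, n, replace = TRUE)
  p <- sample(0:3, n, replace = TRUE)
  r <- evaluate(label_vector(paste0("s", 1:n), y,
                             class_names = paste0("c", 1:4)),
                label_vector(paste0("s", 1:n), p,
                             class_names = paste0("c", 1:4)))
  # 3-sigma binomial band around 25%
  expect_lt(abs(r$accuracy - 25), 300 * sqrt(0.25 * 0.75 / n))
})
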