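test_that("built models report the shapes the trace predicts", {
  m <- tiny_model()
  set.seed(1)
  X <- matrix(rnorm(5 * 38), 5, 38)
  lat <- encode(m, X, allow_untrained = TRUE)
  # two branches of 4 positions x 4 channels concatenated along positions
  expect_equal(dim(lat), c(5L, 8L, 4L))
  expect_equal(attr(lat, "block_positions"), c(4L, 4L))
  rec <- reconstruct(m, X, allow_untrained = TRUE)
  expect_equal(dim(rec), c(5L, 38L))
  # batch-size independence
  lat1 <- encode(m, X[2, , drop = FALSE], allow_untrained = TRUE)
  expect_equal(dim(lat1), c(1L, 8L, 4L))
  expect_equal(lat1[1, , ], lat[2, , ], tolerance = 1e-12)
})

test_that("parameter initialization is deterministic in the seed", {
  m1 <- tiny_model(seed = 9)
  m2 <- tiny_model(seed = 9)
  m3 <- tiny_model(seed = 10)
  nms <- sort(ls(m1$params))
  for (nm in nms) {
    expect_identical(get(nm, envir = m1$params),
                     get(nm, envir = m2$params))
  }
  expect_false(identical(get("b1.enc.dense1.W", envir = m1$params),
                         get("b1.enc.dense1.W", envir = m3$params)))
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("caemgbdt")
  m <- tiny_model(attention = TRUE, seed = 5)
  set.seed(3)
  X <- matrix(rnorm(4 * 38), 4, 38)
  fwd <- ns$caem_forward(m, X, want_cache = TRUE)
  gr <- ns$caem_backward(m, fwd, X)
  lossfun <- function() {
    f <- ns$caem_forward(m, X)
    sum((X - f$xhat)^2) / (2 * nrow(X))
  }
  pe <- m$params
  eps <- 1e-6
  set.seed(12)
  for (nm in sort(ls(pe))) {
    p <- get(nm, envir = pe)
    g <- get(nm, envir = gr)
    for (i in sample(length(p), min(3, length(p)))) {
      orig <- p[i]
      p[i] <- orig + eps; assign(nm, p, envir = pe); up <- lossfun()
      p[i] <- orig - eps; assign(nm, p, envir = pe); dn <- lossfun()
      p[i] <- orig; assign(nm, p, envir = pe)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])),
                1e-3)
    }
  }
})

test_that("training descends on low-rank data and logs every epoch", {
  # rank-2 signal plus small noise: latent capacity (2 x 4 x 4) exceeds it
  set.seed(21)
  n <- 32
  scores <- matrix(rnorm(n * 2), n)
  load1 <- matrix(rnorm(2 * 38, sd = 2), 2)
  X <- standardize(scores %*% load1 + matrix(rnorm(n * 38, sd = 0.1), n))
  m <- tiny_model(seed = 2)
  m <- train_cae(m, X, epochs = 40, lambda = 1e-4, seed = 2)
  expect_length(m$training_log, 40L)
  expect_lt(m$training_log[40], m$training_log[1])
  expect_true(all(is.finite(m$training_log)))
  # final reconstruction beats the mean predictor
  rec <- reconstruct(m, X)
  mse <- mean((X$values - rec)^2)
  expect_lt(mse, mean((X$values - mean(X$values))^2))
})

test_that("training is a no-op at epochs = 0 and deterministic in the seed", {
  m <- tiny_model(seed = 4)
  before <- get("b1.enc.dense1.W", envir = m$params)
  m0 <- train_cae(m, matrix(rnorm(6 * 38), 6), epochs = 0)
  expect_identical(get("b1.enc.dense1.W", envir = m0$params), before)
  expect_length(m0$training_log, 0L)

  set.seed(31)
  X <- matrix(rnorm(20 * 38), 20)
  log1 <- train_cae(tiny_model(seed = 6), X, epochs = 6,
                    seed = 6)$training_log
  log2 <- train_cae(tiny_model(seed = 6), X, epochs = 6,
                    seed = 6)$training_log
  expect_identical(log1, log2)
})

test_that("shape violations are reported as errors", {
  m <- tiny_model()
  expect_error(train_cae(m, matrix(0, 4, 10), epochs = 1), "expects 38")
  expect_error(encode(m, matrix(0, 4, 10), allow_untrained = TRUE),
               "expects 38")
  expect_error(encode(m, matrix(0, 4, 38)), "untrained")
  # mismatched latent channel counts across branches
  s1 <- arch_spec(16L, list(list(filters = 4L, kernel = 3L, stride = 2L,
                                 pool = 2L)))
  s2 <- arch_spec(16L, list(list(filters = 2L, kernel = 3L, stride = 2L,
                                 pool = 2L)))
  expect_error(build_cae(list(s1, s2), c(20L, 20L)), "channel count")
})

test_that("the attention block sits between encoder and decoder", {
  m_att <- tiny_model(attention = TRUE, seed = 8)
  m_none <- tiny_model(attention = FALSE, seed = 8)
  set.seed(2)
  X <- matrix(rnorm(4 * 38), 4, 38)
  lat_att <- encode(m_att, X, allow_untrained = TRUE)
  lat_raw <- encode(m_att, X, apply_attention = FALSE,
                    allow_untrained = TRUE)
  lat_none <- encode(m_none, X, allow_untrained = TRUE)
  # without applying attention the latent equals the attention-free model's
  expect_equal(as.numeric(lat_raw), as.numeric(lat_none),
               tolerance = 1e-12)
  # attention attenuates but never changes shape
  expect_equal(dim(lat_att), dim(lat_raw))
  expect_true(all(abs(lat_att) <= abs(lat_raw) + 1e-12))
})

test_that("training a model with attention updates the attention weights", {
  m <- tiny_model(attention = TRUE, seed = 11)
  w_before <- get("cbam.W0", envir = m$params)
  set.seed(5)
  m <- train_cae(m, matrix(rnorm(16 * 38), 16), epochs = 3, seed = 3)
  expect_false(identical(get("cbam.W0", envir = m$params), w_before))
})
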