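# Independent oracle for the full attention block, written as plain loops
# over the defining pooled-MLP / pooled-convolution computations.
cbam_oracle <- function(F, W0, W1, Wsp, order = "channel_first") {
  sig <- function(z) 1 / (1 + exp(-z))
  channel <- function(F) {
    avg <- apply(F, 2, mean)
    mx <- apply(F, 2, max)
    mlp <- function(v) pmax(v %*% W0, 0) %*% W1
    drop(sig(mlp(rbind(avg)) + mlp(rbind(mx))))
  }
  spatial <- function(F) {
    avg <- apply(F, 1, mean)
    mx <- apply(F, 1, max)
    k <- dim(Wsp)[1]
    half <- (k - 1) / 2
    L <- nrow(F)
    out <- numeric(L)
    for (pos in seq_len(L)) {
      acc <- 0
      for (j in seq_len(k)) {
        src <- pos + j - 1 - half
        if (src >= 1 && src <= L) {
          acc <- acc + avg[src] * Wsp[j, 1, 1] + mx[src] * Wsp[j, 2, 1]
        }
      }
      out[pos] <- sig(acc)
    }
    out
  }
  if (order == "channel_first") {
    F1 <- sweep(F, 2, channel(F), "*")
    sweep(F1, 1, spatial(F1), "*")
  } else {
    F1 <- sweep(F, 1, spatial(F), "*")
    sweep(F1, 2, channel(F1), "*")
  }
}

test_that("zero-weight attention yields flat 0.5 maps and 0.25 scaling", {
  ca <- channel_attention_module(4, ratio = 2, init = "zero")
  sa <- spatial_attention_module(7, init = "zero")
  set.seed(2)
  F <- matrix(rnorm(16 * 4), 16, 4)
  expect_equal(channel_attention(F, ca), rep(0.5, 4))
  expect_equal(spatial_attention(F, sa), rep(0.5, 16))
  expect_equal(apply_cbam(F, ca, sa), 0.25 * F)
  # multiplicative: zero input stays zero
  expect_equal(apply_cbam(matrix(0, 16, 4), ca, sa), matrix(0, 16, 4))
})

test_that("attention maps lie strictly in (0,1) and only attenuate", {
  for (s in 1:5) {
    ca <- channel_attention_module(4, ratio = 8, seed = s)
    sa <- spatial_attention_module(7, seed = s + 50)
    set.seed(s + 100)
    F <- matrix(rnorm(16 * 4, sd = 2), 16, 4)
    cm <- channel_attention(F, ca)
    sm <- spatial_attention(F, sa)
    expect_true(all(cm > 0 & cm < 1))
    expect_true(all(sm > 0 & sm < 1))
    out <- apply_cbam(F, ca, sa)
    expect_equal(dim(out), dim(F))
    expect_true(all(abs(out) <= abs(F) + 1e-12))
  }
})

test_that("channel attention hidden width is channels/ratio floored at 1", {
  expect_equal(channel_attention_module(4, ratio = 8)$hidden, 1L)
  expect_equal(channel_attention_module(32, ratio = 8)$hidden, 4L)
})

test_that("a hand-computable channel toy matches the pooled-MLP formula", {
  # 2 positions x 2 channels; identity-like MLP (hidden width 2)
  F <- matrix(c(1, 3, 0, 0), 2, 2)
  ca <- channel_attention_module(2, ratio = 1, init = "zero")
  ca$W0 <- diag(2)
  ca$W1 <- diag(2)
  # avg = (2, 0), max = (3, 0); relu passes both; sum = (5, 0)
  expect_equal(channel_attention(F, ca),
               1 / (1 + exp(-c(5, 0))))
})

test_that("a 4-position spatial toy matches a by-hand convolution", {
  F <- matrix(c(1, 2, 3, 4), 4, 1) # single channel: avg = max = column
  sa <- spatial_attention_module(3, init = "zero")
  sa$W <- array(1, c(3, 2, 1)) # ones kernel over both pooled channels
  # pooled stack rows: (x, x); same-padded ones-conv of (1,2,3,4) doubled
  conv <- c(1 + 2, 1 + 2 + 3, 2 + 3 + 4, 3 + 4) * 2
  expect_equal(spatial_attention(F, sa), 1 / (1 + exp(-conv)))
})

test_that("apply_cbam equals the independent sequential oracle", {
  for (s in 1:8) {
    ca <- channel_attention_module(4, ratio = 2, seed = s)
    sa <- spatial_attention_module(7, seed = s + 10)
    set.seed(s + 20)
    F <- matrix(rnorm(16 * 4), 16, 4)
    expect_lt(max(abs(apply_cbam(F, ca, sa) -
                        cbam_oracle(F, ca$W0, ca$W1, sa$W))), 1e-6)
    # reversed order (ablation flag) matches its own oracle and differs
    rev_out <- apply_cbam(F, ca, sa, order = "spatial_first")
    expect_lt(max(abs(rev_out -
                        cbam_oracle(F, ca$W0, ca$W1, sa$W,
                                    "spatial_first"))), 1e-6)
    expect_gt(max(abs(rev_out - apply_cbam(F, ca, sa))), 1e-10)
  }
})

test_that("degenerate single-position input yields a single-entry map", {
  sa <- spatial_attention_module(7, seed = 1)
  F <- matrix(c(1, 2, 3), 1, 3)
  expect_length(spatial_attention(F, sa), 1L)
})

test_that("batched and per-sample attention agree", {
  ca <- channel_attention_module(4, ratio = 2, seed = 3)
  sa <- spatial_attention_module(5, seed = 4)
  set.seed(6)
  Fb <- array(rnorm(3 * 8 * 4), c(3, 8, 4))
  out_b <- apply_cbam(Fb, ca, sa)
  for (i in 1:3) {
    Fi <- matrix(Fb[i, , ], 8, 4)
    expect_equal(matrix(out_b[i, , ], 8, 4), apply_cbam(Fi, ca, sa),
                 tolerance = 1e-12)
  }
})
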