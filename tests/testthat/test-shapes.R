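test_that("conv_out_len follows the same/valid padding rules", {
  expect_equal(conv_out_len(512, 3, 2, "same"), 256L)
  expect_equal(conv_out_len(5, 3, 2, "same"), 3L)
  expect_equal(conv_out_len(7, 3, 2, "valid", pad = 0), 3L)
  expect_equal(conv_out_len(128, 3, 2, "same"), 64L)
  expect_error(conv_out_len(2, 5, 1, "valid", pad = 0), "output length")
})

test_that("tconv_out_len implements stride*(L-1) + kernel - 2*padding", {
  expect_equal(tconv_out_len(64, 1, 3, 1), 64L)
  expect_equal(tconv_out_len(64, 2, 3, 0), 129L)
  expect_equal(tconv_out_len(1, 1, 1, 0), 1L)
  expect_error(tconv_out_len(1, 1, 3, 2), "output length")
})

test_that("the preset encoder stacks reduce to a 16 x 4 latent", {
  # wide stack on the gene-expression width: 512 -> 256 -> 128 -> 64 -> 16
  tr <- shape_trace(arch_preset("brca_wide"), 17814)
  enc <- tr[tr$stage == "encoder", ]
  expect_equal(enc$out_len,
               c(17814L, 512L, 256L, 128L, 64L, 16L))
  expect_equal(attr(tr, "latent_shape"),
               c(positions = 16L, channels = 4L))
  # and identically on the methylation width
  expect_equal(attr(shape_trace(arch_preset("brca_wide"), 23094),
                    "latent_shape"),
               c(positions = 16L, channels = 4L))
  # narrow stack: 128 -> 64 -> 16
  tr2 <- shape_trace(arch_preset("brca_mirna"), 354)
  expect_equal(tr2[tr2$stage == "encoder", "out_len"],
               c(354L, 128L, 64L, 16L))
  expect_equal(attr(tr2, "latent_shape"),
               c(positions = 16L, channels = 4L))
  # shared stack on every GBM block width
  for (d in c(12042L, 534L, 1305L)) {
    expect_equal(latent_shape(arch_preset("gbm"), d),
                 c(positions = 16L, channels = 4L))
  }
})

test_that("the decoder trace mirrors back to the input width", {
  tr <- shape_trace(arch_preset("brca_wide"), 17814)
  dec <- tr[tr$stage == "decoder", ]
  # upsample x4 -> 64, tconv -> 128 (4 ch), upsample x2 -> 256,
  # tconv -> 512 (16 ch), collapse to 1 ch, dense restores 17,814
  expect_equal(dec$out_len, c(64L, 128L, 256L, 512L, 512L, 17814L))
  expect_equal(dec$channels, c(4L, 4L, 4L, 16L, 1L, 1L))
})

test_that("degenerate geometries raise shape errors naming the layer", {
  bad_pool <- arch_spec(16L, list(list(filters = 2L, kernel = 3L,
                                       stride = 2L, pool = 32L)))
  expect_error(shape_trace(bad_pool, 64), "pool")
  expect_error(shape_trace(arch_preset("gbm"), 100),
               "final dense width")
  # a pool that does not divide the length cannot mirror
  odd <- arch_spec(24L, list(list(filters = 2L, kernel = 3L, stride = 2L,
                                  pool = 5L)))
  expect_error(shape_trace(odd, 24), "mirror")
})

test_that("architecture specs serialize to YAML and back", {
  sp <- arch_preset("brca_wide")
  p <- tempfile(fileext = ".yaml")
  arch_to_yaml(sp, p)
  sp2 <- arch_from_yaml(p)
  expect_equal(sp2$dense_units, sp$dense_units)
  expect_equal(sp2$conv_blocks, sp$conv_blocks)
  expect_equal(sp2$name, "brca_wide")
})

test_that("arch_spec validates its block parameters", {
  expect_error(arch_spec(64L, list(list(filters = 0L, kernel = 3L,
                                        stride = 1L, pool = 1L))),
               ">= 1")
  expect_error(arch_spec(64L, list(list(filters = 2L, kernel = 4L,
                                        stride = 1L, pool = 1L))),
               "odd")
})
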