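test_that("generated blocks match the configured shapes and align", {
  cfg <- synthetic_config(n_samples = 24, block_dims = c(50L, 20L, 30L),
                          K = 3, seed = 7)
  dat <- generate_multiomics(cfg)
  expect_length(dat$blocks, 3L)
  expect_equal(vapply(dat$blocks, function(b) nrow(b$values), integer(1)),
               c(50L, 20L, 30L))
  ids <- dat$blocks[[1]]$sample_ids
  for (b in dat$blocks) expect_identical(b$sample_ids, ids)
  expect_identical(dat$labels$sample_ids, ids)
  expect_equal(vapply(dat$mask, sum, numeric(1)),
               round(0.1 * c(50, 20, 30)))
  # balanced classes by default
  expect_equal(unname(table(dat$labels$labels)), rep(8L, 3),
               ignore_attr = TRUE)
})

test_that("reference-shaped fixtures reproduce the published dimensions", {
  gbm <- caemgbdt:::fixture_config("gbm_shaped")
  expect_equal(gbm$block_dims, c(12042L, 534L, 1305L))
  expect_equal(gbm$n_samples, 213L)
  brca <- caemgbdt:::fixture_config("brca_shaped")
  expect_equal(brca$block_dims, c(17814L, 354L, 23094L))
  expect_equal(sum(brca$block_dims), 41262L)
  expect_equal(brca$n_samples, 104L)
})

test_that("generation is bitwise reproducible from the seed", {
  cfg <- synthetic_config(30, c(40L, 25L), K = 2, seed = 11)
  a <- generate_multiomics(cfg)
  b <- generate_multiomics(cfg)
  expect_identical(a$blocks[[1]]$values, b$blocks[[1]]$values)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$mask, b$mask)
  cfg2 <- synthetic_config(30, c(40L, 25L), K = 2, seed = 12)
  expect_false(identical(generate_multiomics(cfg2)$blocks[[1]]$values,
                         a$blocks[[1]]$values))
})

test_that("class proportions are honored by largest-remainder rounding", {
  cfg <- synthetic_config(10, c(20L), K = 3,
                          class_proportions = c(0.5, 0.3, 0.2), seed = 2)
  dat <- generate_multiomics(cfg)
  expect_equal(unname(table(dat$labels$labels)), c(5L, 3L, 2L),
               ignore_attr = TRUE)
  expect_error(synthetic_config(10, 20L, K = 2,
                                class_proportions = c(0.6, 0.6)),
               "summing to 1")
  expect_error(synthetic_config(3, 20L, K = 5), "exceeds n_samples")
})

test_that("planted informative features carry the largest class contrasts", {
  cfg <- synthetic_config(n_samples = 90, block_dims = 400L, K = 3,
                          informative_frac = 0.1, effect_size = 3,
                          seed = 5)
  dat <- generate_multiomics(cfg)
  X <- dat$blocks[[1]]$values # features x samples
  y <- dat$labels$labels
  # rank features by between-class spread of class means
  spread <- apply(X, 1, function(v) {
    mu <- tapply(v, y, mean)
    max(mu) - min(mu)
  })
  n_inf <- sum(dat$mask[[1]])
  top <- order(spread, decreasing = TRUE)[seq_len(n_inf)]
  recovered <- mean(dat$mask[[1]][top])
  expect_gt(recovered, 0.9)
})

test_that("fixtures round-trip through the loader", {
  dir <- file.path(tempdir(), "fx_roundtrip")
  fx <- make_fixture("tiny", dir)
  expect_true(all(file.exists(fx$paths)))
  reloaded <- Map(load_omics, fx$paths, fx$omics_types)
  for (b in seq_along(reloaded)) {
    expect_equal(reloaded[[b]]$values, fx$blocks[[b]]$values,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(reloaded[[b]]$sample_ids, fx$blocks[[b]]$sample_ids)
  }
  labs <- read_labels(fx$labels_path)
  expect_identical(labs$labels, fx$labels$labels)
  manifest <- jsonlite::read_json(fx$manifest_path)
  expect_equal(manifest$config$seed, 42L)
  unlink(dir, recursive = TRUE)
})

test_that("end-to-end accuracy rises with the planted effect size", {
  # small blocks and few epochs keep this a statistical, not exhaustive,
  # check; means over 5 seeds, allowing small dips near chance level
  effect_sizes <- c(0, 0.5, 1, 2, 4)
  acc <- matrix(NA_real_, length(effect_sizes), 5)
  for (i in seq_along(effect_sizes)) {
    for (s in 1:5) {
      cfg <- synthetic_config(n_samples = 48, block_dims = c(60L, 40L),
                              K = 3, informative_frac = 0.2,
                              effect_size = effect_sizes[i],
                              seed = 100 * s)
      dat <- generate_multiomics(cfg)
      d <- write_dataset(dat, file.path(tempdir(),
                                        sprintf("mono_%d_%d", i, s)))
      run <- run_train(run_config(
        data = list(paths = d$paths, labels = d$labels,
                    omics_types = d$omics_types),
        preset = "auto", epochs = 8, scheme = "ratio_3_1", seed = s,
        gbdt = gbdt_config(n_estimators = 80),
        out_dir = file.path(tempdir(), sprintf("mono_out_%d_%d", i, s))))
      acc[i, s] <- run$summary$accuracy$mean
    }
  }
  means <- rowMeans(acc)
  expect_true(all(diff(means) >= -5)) # nondecreasing up to noise (in %)
  expect_gt(means[length(means)] - means[1], 30)
  expect_gt(means[length(means)], 90)
})
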