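test_that("make_pairs pairs tiles with their high-coverage targets", {
  co <- tiny_cohort(n_cells = 3L, n_bins = 40L, depth = 8000L, seed = 21L)
  ps <- make_pairs(co$cells, ratio = 1, seed = 5, w = 16L, k = 10L)
  # ratio 1: the target equals the central crop of the input tile
  for (p in ps$pairs) expect_equal(p$central, p$target, tolerance = 1e-12)
  expect_length(ps$pairs, 3L * ceiling(40 / 10))

  ps9 <- make_pairs(co$cells, ratio = 9, seed = 5, w = 16L, k = 10L)
  # thinning bound: targets dominate inputs' central crops (monotone normalization)
  for (p in ps9$pairs) expect_true(all(p$target >= p$central - 1e-12))
  expect_error(make_pairs(list(), 2), "empty")
  expect_error(make_pairs(co$cells, 0.5), "ratio")
})

test_that("epochs = 0 returns an initialized checkpoint and empty history", {
  co <- tiny_cohort(n_cells = 3L, n_bins = 40L, depth = 8000L, seed = 21L)
  ps <- make_pairs(co$cells, ratio = 2, seed = 5, w = 16L, k = 10L)
  gcfg <- generator_config(window = 16L, central = 10L)
  res <- train_gan(ps, gcfg, discriminator_config(),
                   train_config(epochs = 0L, seed = 2L))
  expect_s3_class(res$checkpoint, "schic_checkpoint")
  expect_equal(nrow(res$history), 0L)
  expect_equal(res$checkpoint$cap, ps$cap)
})

test_that("training is deterministic given the seed (GAN path included)", {
  co <- tiny_cohort(n_cells = 4L, n_bins = 30L, depth = 6000L, seed = 22L)
  ps <- make_pairs(co$cells, ratio = 4, seed = 9, w = 12L, k = 8L)
  gcfg <- generator_config(window = 12L, central = 8L)
  tcfg <- train_config(epochs = 2L, batch_size = 4L, lambda_adv = 1,
                       seed = 77L, validation_fraction = 0.25)
  r1 <- train_gan(ps, gcfg, discriminator_config(), tcfg)
  r2 <- train_gan(ps, gcfg, discriminator_config(), tcfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$checkpoint$gparams, r2$checkpoint$gparams)
})

test_that("supervised training over-fits a single repeated pair (non-increasing L1)", {
  co <- tiny_cohort(n_cells = 1L, n_bins = 12L, depth = 4000L, seed = 23L)
  ps <- make_pairs(co$cells, ratio = 4, seed = 3, w = 12L, k = 8L)
  ps$pairs <- rep(ps$pairs[1], 4)
  gcfg <- generator_config(window = 12L, central = 8L)
  tcfg <- train_config(epochs = 25L, batch_size = 4L, lambda_adv = 0,
                       lr_g = 1e-4, seed = 5L, validation_fraction = 0)
  res <- train_gan(ps, gcfg, discriminator_config(), tcfg)
  g <- res$history$g_loss
  expect_true(all(diff(g) <= 0.05 * g[-length(g)]))
  expect_lt(g[length(g)], g[1])
})

test_that("a from-scratch GAN discriminator separates real from downsampled tiles", {
  sp <- synthetic_spec(n_bins = 60L, depth_per_cell = 15000L, n_cells = 10L,
                       seed = 3L)
  cells <- simulate_cohort(sp)
  ps <- make_pairs(cells, ratio = 9, seed = 3L, w = 40L, k = 28L)
  res <- train_gan(ps, generator_config(), discriminator_config(),
                   train_config(epochs = 10L, lambda_adv = 1,
                                downsample_ratio = 9, seed = 1L,
                                validation_fraction = 0.2))
  ck <- res$checkpoint
  idx <- which(vapply(ps$pairs, function(p) p$cell, integer(1)) %in% ck$val_cells)
  sc_real <- mean(vapply(idx, function(i) {
    discriminator_forward(ps$pairs[[i]]$target, ck$dparams, ck$dcfg)
  }, numeric(1)))
  sc_input <- mean(vapply(idx, function(i) {
    discriminator_forward(ps$pairs[[i]]$central, ck$dparams, ck$dcfg)
  }, numeric(1)))
  expect_gt(sc_real, sc_input)
})

test_that("checkpoints round-trip bitwise through save/load", {
  co <- tiny_cohort(n_cells = 3L, n_bins = 40L, depth = 8000L, seed = 21L)
  ps <- make_pairs(co$cells, ratio = 2, seed = 5, w = 16L, k = 10L)
  gcfg <- generator_config(window = 16L, central = 10L)
  res <- train_gan(ps, gcfg, discriminator_config(),
                   train_config(epochs = 1L, lambda_adv = 0, seed = 3L))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(res$checkpoint, f)
  ck2 <- load_checkpoint(f)
  m <- co$cells[[1]]
  expect_identical(enhance(res$checkpoint, m)$counts, enhance(ck2, m)$counts)
})

test_that("enhance outputs symmetric nonnegative matrices with input pass-through", {
  co <- tiny_cohort(n_cells = 3L, n_bins = 40L, depth = 8000L, seed = 21L)
  ps <- make_pairs(co$cells, ratio = 2, seed = 5, w = 16L, k = 10L)
  gcfg <- generator_config(window = 16L, central = 10L)
  res <- train_gan(ps, gcfg, discriminator_config(),
                   train_config(epochs = 1L, lambda_adv = 0, seed = 3L))
  m <- co$cells[[2]]
  em <- enhance(res$checkpoint, m)
  expect_identical(em$counts, t(em$counts))
  expect_true(all(em$counts >= 0))
  # outside the enhanced diagonal band the input passes through exactly
  outside <- !enhanced_band_mask(40L, gcfg$central)
  expect_true(any(outside))
  expect_identical(em$counts[outside], m$counts[outside] * 1.0)
  expect_error(enhance(res$checkpoint, rand_sym_cm(6)), "smaller")
})
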