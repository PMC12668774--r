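test_that("rank-one extraction has the contracted shapes and zero behavior", {
  for (n in c(8L, 16L, 40L)) {
    pars <- rank_one_params(n, c_in = 2L, channels = 4L, seed = n)
    x <- array(abs(stats::rnorm(n * n * 2)), c(n, n, 2L))
    bundle <- rank_one_extract(x, pars)
    expect_equal(dim(bundle$vectors), c(n, 4L))
    expect_true(all(bundle$channel_weights >= 0))
    zero <- rank_one_extract(array(0, c(n, n, 2L)), pars)
    expect_true(all(zero$vectors == 0))
  }
  pars <- rank_one_params(8L, 1L, 2L)
  expect_error(rank_one_extract(matrix(0, 9, 9), pars), "mismatch")
})

test_that("an all-ones n x 1 kernel with identity refinements yields column sums", {
  n <- 6L
  pars <- rank_one_params(n, c_in = 1L, channels = 1L, identity_refine = TRUE)
  pars$nx1W <- matrix(1, n, 1L)
  pars$nx1b <- 0
  set.seed(2)
  x <- matrix(stats::runif(n * n), n)        # nonnegative, ReLU-transparent
  bundle <- rank_one_extract(x, pars)
  expect_equal(drop(bundle$vectors), colSums(x), tolerance = 1e-12)
})

test_that("rank-one reconstruction is a bitwise-symmetric rank-1 outer product", {
  b <- list(vectors = matrix(c(1, 2), 2, 1), channel_weights = 1)
  expect_equal(rank_one_reconstruct(b)[, , 1], matrix(c(1, 2, 2, 4), 2))

  set.seed(9)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    C <- sample(1:6, 1)
    b <- list(vectors = matrix(stats::rnorm(n * C), n, C),
              channel_weights = stats::runif(C, 0, 3))
    out <- rank_one_reconstruct(b)
    for (c in seq_len(C)) {
      ch <- out[, , c]
      expect_identical(ch, t(ch))
      sv <- svd(ch)$d
      expect_lt(sv[2], 1e-8 * max(sv[1], 1e-300))
    }
  }
  expect_error(rank_one_reconstruct(list(vectors = matrix(1, 2, 1),
                                         channel_weights = -1)), "nonnegative")
})

test_that("SE recalibration gates in (0,1), preserves symmetry, bypass is identity", {
  C <- 8L
  pars <- se_params(C, reduction = 4L, seed = 5)
  x <- array(stats::rnorm(10 * 10 * C), c(10, 10, C))
  for (c in seq_len(C)) x[, , c] <- (x[, , c] + t(x[, , c])) / 2
  out <- se_recalibrate(x, pars)
  expect_identical(se_recalibrate(x, pars, bypass = TRUE), x)
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  for (c in seq_len(C)) expect_identical(out[, , c], t(out[, , c]))
  expect_error(se_params(6L, reduction = 4L), "divide")
  expect_error(se_recalibrate(x, se_params(4L, 2L)), "channel count")
})

test_that("generator output has contracted shape, symmetry and finiteness", {
  for (wk in list(c(12L, 8L), c(40L, 28L))) {
    cfg <- generator_config(window = wk[1], central = wk[2])
    pars <- init_generator_params(cfg, seed = 3)
    out0 <- generator_forward(matrix(0, wk[1], wk[1]), matrix(0, wk[2], wk[2]), pars, cfg)
    expect_true(all(is.finite(out0)))
    expect_equal(dim(out0), c(wk[2], wk[2]))
    set.seed(wk[1])
    ot <- matrix(stats::runif(wk[1]^2), wk[1]); ot <- (ot + t(ot)) / 2
    ct <- matrix(stats::runif(wk[2]^2), wk[2]); ct <- (ct + t(ct)) / 2
    out <- generator_forward(ot, ct, pars, cfg)
    expect_identical(out, t(out))
    expect_true(all(out >= 0 & out <= cfg$final_cap))
  }
  cfg <- generator_config(window = 12L, central = 8L)
  pars <- init_generator_params(cfg, 1)
  bad <- matrix(NA_real_, 12, 12)
  expect_error(generator_forward(bad, matrix(0, 8, 8), pars, cfg), "non-finite")
  expect_error(generator_forward(matrix(0, 10, 10), matrix(0, 8, 8), pars, cfg), "shape")
})

test_that("neither branch is dead: inconsistent inputs change the output", {
  cfg <- generator_config(window = 12L, central = 8L)
  pars <- init_generator_params(cfg, seed = 8)
  set.seed(21)
  otA <- matrix(stats::runif(144), 12); otA <- (otA + t(otA)) / 2
  otB <- matrix(stats::runif(144), 12); otB <- (otB + t(otB)) / 2
  ctA <- otA[3:10, 3:10]
  ctB <- otB[3:10, 3:10]
  base <- generator_forward(otA, ctA, pars, cfg)
  expect_gt(max(abs(generator_forward(otA, ctB, pars, cfg) - base)), 0)
  expect_gt(max(abs(generator_forward(otB, ctA, pars, cfg) - base)), 0)
})

test_that("generator is invariant under input transposition (asymmetric probe)", {
  cfg <- generator_config(window = 12L, central = 8L)
  pars <- init_generator_params(cfg, seed = 4)
  set.seed(33)
  ot <- matrix(stats::runif(144), 12)        # deliberately asymmetric
  ct <- matrix(stats::runif(64), 8)
  expect_identical(generator_forward(ot, ct, pars, cfg),
                   generator_forward(t(ot), t(ct), pars, cfg))
})

test_that("default generator stays under the parameter budget", {
  expect_lt(n_params(init_generator_params(generator_config(), 1)), 5e5)
})

test_that("discriminator scores are deterministic and finite", {
  dcfg <- discriminator_config()
  pars <- init_discriminator_params(dcfg, seed = 2)
  set.seed(6)
  tile <- matrix(stats::runif(28 * 28), 28)
  s1 <- discriminator_forward(tile, pars, dcfg)
  expect_identical(s1, discriminator_forward(tile, pars, dcfg))
  expect_true(is.finite(s1))
  expect_length(s1, 1L)
  grid <- discriminator_forward(tile, pars, discriminator_config(patch_output = TRUE))
  expect_true(is.matrix(grid) && all(is.finite(grid)))
  expect_equal(mean(grid), s1)
})

test_that("autodiff gradients match finite differences on a small generator", {
  cfg <- generator_config(window = 10L, central = 6L)
  gp <- init_generator_params(cfg, seed = 13)
  set.seed(13)
  ot <- matrix(stats::runif(100), 10); ot <- (ot + t(ot)) / 2
  ct <- ot[3:8, 3:8]
  tg <- matrix(stats::runif(36), 6); tg <- (tg + t(tg)) / 2
  loss_of <- function(params) {
    tape <- schicenhance:::ad_tape()
    P <- schicenhance:::params_to_nodes(tape, params, FALSE)
    out <- schicenhance:::generator_graph(tape, P, array(ot, c(10, 10, 1)),
                                          array(ct, c(6, 6, 1)), cfg)
    schicenhance:::ad_l1_loss(tape, out, array(tg, c(6, 6, 1)))$value
  }
  tape <- schicenhance:::ad_tape()
  P <- schicenhance:::params_to_nodes(tape, gp, TRUE)
  out <- schicenhance:::generator_graph(tape, P, array(ot, c(10, 10, 1)),
                                        array(ct, c(6, 6, 1)), cfg)
  l <- schicenhance:::ad_l1_loss(tape, out, array(tg, c(6, 6, 1)))
  schicenhance:::ad_backward(tape, l)
  eps <- 1e-6
  for (nm in c("outer.conv1W", "central.conv2W", "outer.seW2", "central.nx1W",
               "outer.r1bW", "central.wraw", "fuse1W", "fuse2b")) {
    g <- P[[nm]]$grad
    expect_false(is.null(g), info = nm)
    idx <- sample(length(gp[[nm]]), min(3L, length(gp[[nm]])))
    for (i in idx) {
      up <- gp; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- gp; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_lt(abs(fd - g[i]), 1e-4 * max(1, abs(fd)))
    }
  }
})
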